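#' Source-filter voice synthesis
#'
#' A glottal pulse train at the fundamental frequency is filtered through an
#' all-pole vocal-tract model (one two-pole resonator per formant, 80 Hz
#' bandwidths), white Gaussian noise is added, and the waveform is
#' peak-normalized to 0.9. Randomness (the noise) comes from the current RNG
#' state; wrap the call in a seeded context for reproducibility.
#'
#' @param f0 fundamental frequency in `[50, 500]` Hz.
#' @param formants ascending resonance frequencies in Hz, below `sr/2`.
#' @param duration seconds.
#' @param sample_rate Hz.
#' @param noise_sd additive white-noise standard deviation (pre-normalization).
#' @param bandwidths resonator bandwidths in Hz (default 80 each).
#' @return Numeric waveform.
#' @export
synthesize_voice <- function(f0, formants, duration, sample_rate,
                             noise_sd = 0, bandwidths = rep(80, length(formants))) {
  if (!is_scalar_num(f0) || f0 < 50 || f0 > 500)
    stop_mf("f0 must be in [50, 500] Hz (got %.3g)", f0)
  if (is.unsorted(formants, strictly = TRUE) || any(formants >= sample_rate / 2))
    stop_mf("formants must be strictly ascending and below sample_rate/2")
  n <- as.integer(round(duration * sample_rate))
  if (n < 1L) stop_mf("duration too short")
  period <- as.integer(round(sample_rate / f0))
  x <- numeric(n)
  x[seq(1L, n, by = period)] <- 1
  for (i in seq_along(formants)) {
    r <- exp(-pi * bandwidths[i] / sample_rate)
    th <- 2 * pi * formants[i] / sample_rate
    x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r^2),
                                  method = "recursive"))
  }
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  peak <- max(abs(x))
  if (peak > 0) x <- 0.9 * x / peak
  x
}

# Deterministic canonical layouts: facial landmarks on an ellipse, body
# joints on a rough standing skeleton. Pixel coordinates, origin top-left.
default_base_pose <- function(modality) {
  if (modality == "face") {
    a <- seq(0, 2 * pi, length.out = 69L)[-69L]
    cbind(x = 320 + 80 * cos(a), y = 240 + 100 * sin(a))
  } else {
    cbind(x = 320 + 60 * cos(seq(0, 2 * pi, length.out = 19L)[-19L]),
          y = 240 + 150 * seq(-1, 1, length.out = 18L))
  }
}

#' Generate oscillatory keypoint motion
#'
#' Each point oscillates sinusoidally about its base position along a
#' per-point direction, with a per-point phase offset, plus Gaussian pixel
#' jitter; confidences are drawn uniformly in `[0.6, 1]`. Uses the current
#' RNG state.
#'
#' @param modality `"face"` (68 points) or `"gait"` (18 points).
#' @param base_pose optional `points x 2` matrix of rest positions.
#' @param motion_amp oscillation amplitude in pixels; scalar or per-point.
#' @param motion_freq oscillation frequency in Hz; scalar or per-point.
#' @param noise_sd per-axis Gaussian jitter in pixels.
#' @param duration seconds (> 0).
#' @param fps frames per second (> 0).
#' @return A [keypoint_sequence()].
#' @export
generate_keypoint_motion <- function(modality = c("face", "gait"),
                                     base_pose = NULL, motion_amp = 2,
                                     motion_freq = 1, noise_sd = 0.5,
                                     duration = 10, fps = 25) {
  modality <- match.arg(modality)
  if (!is_scalar_num(duration) || duration <= 0) stop_mf("duration must be positive")
  if (!is_scalar_num(fps) || fps <= 0) stop_mf("fps must be positive")
  p <- points_for_modality(modality)
  if (is.null(base_pose)) base_pose <- default_base_pose(modality)
  amp <- rep_len(motion_amp, p)
  frq <- rep_len(motion_freq, p)
  nfr <- as.integer(round(duration * fps))
  tt <- (seq_len(nfr) - 1L) / fps
  phase <- runif(p, 0, 2 * pi)
  dir <- runif(p, 0, 2 * pi)
  osc <- sin(outer(tt, frq * 2 * pi) + rep(phase, each = nfr)) *
    rep(amp, each = nfr)
  x <- rep(base_pose[, 1L], each = nfr) + osc * rep(cos(dir), each = nfr)
  y <- rep(base_pose[, 2L], each = nfr) + osc * rep(sin(dir), each = nfr)
  if (noise_sd > 0) {
    x <- x + rnorm(length(x), sd = noise_sd)
    y <- y + rnorm(length(y), sd = noise_sd)
  }
  keypoint_sequence(matrix(x, nfr, p), matrix(y, nfr, p),
                    matrix(runif(nfr * p, 0.6, 1), nfr, p), modality, fps)
}

#' Cohort specification
#'
#' Describes a synthetic multimodal cohort: per-indicator prevalence,
#' per-(indicator, modality) effect sizes (standardized mean shifts of the
#' generative parameters), per-modality observation noise, and recording
#' parameters. The defaults mirror the intended recording protocol: one 30 s
#' face stream at 25 fps, one 8 s gait stream, three 1 s voice segments at
#' 16 kHz.
#'
#' @param n_subjects at least 2.
#' @param prevalence scalar or length-10 vector in `(0, 1)` (default 0.5).
#' @param effects scalar, or `10 x 3` matrix (rows = indicators, columns =
#'   face/voice/gait) of standardized effect sizes (default 1).
#' @param noise_sd named vector `c(face=, voice=, gait=)`: pixel jitter for
#'   the keypoint streams, additive waveform noise for voice.
#' @param fps keypoint frame rate.
#' @param sample_rate audio rate in Hz.
#' @param seed master seed; everything downstream derives from it.
#' @param face_duration,gait_duration,voice_segments stream sizes.
#' @return A `CohortSpec`.
#' @export
cohort_spec <- function(n_subjects, prevalence = 0.5, effects = 1,
                        noise_sd = c(face = 0.5, voice = 0.01, gait = 0.5),
                        fps = 25, sample_rate = 16000, seed = 1L,
                        face_duration = 30, gait_duration = 8,
                        voice_segments = 3L) {
  if (!is_scalar_num(n_subjects) || n_subjects < 2) stop_mf("n_subjects must be >= 2")
  prevalence <- rep_len(prevalence, 10L)
  if (any(prevalence <= 0) || any(prevalence >= 1))
    stop_mf("prevalences must be in (0, 1)")
  if (is.null(dim(effects)))
    effects <- matrix(effects, 10L, 3L)
  effects <- as.matrix(effects)
  if (!all(dim(effects) == c(10L, 3L)))
    stop_mf("effects must be scalar or a 10 x 3 matrix")
  dimnames(effects) <- list(indicator_names(), c("face", "voice", "gait"))
  names(prevalence) <- indicator_names()
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 effects = effects, noise_sd = noise_sd, fps = fps,
                 sample_rate = sample_rate, seed = as.integer(seed),
                 face_duration = face_duration, gait_duration = gait_duration,
                 voice_segments = as.integer(voice_segments)),
            class = "CohortSpec")
}

# Generative parameter book. Baseline mean, between-subject sd; an effect of
# size e shifts the parameter by e * sd for each positive indicator mapped to
# it. Face: indicator i owns landmarks 6(i-1)+1 .. 6i (amplitude shift).
# Gait: indicators 1..9 own joint pairs (2i-1, 2i); indicator 10 shifts the
# global gait amplitude. Voice: indicators map to (f0, For1, For2, For3,
# gain, tilt, -f0, -For1, -For2, -For3) mean shifts.
cohort_params <- function() {
  list(face_amp = c(mean = 2, sd = 0.5),
       gait_amp = c(mean = 8, sd = 2),
       f0 = c(mean = 120, sd = 10),
       For1 = c(mean = 700, sd = 40),
       For2 = c(mean = 1200, sd = 60),
       For3 = c(mean = 2600, sd = 80),
       gain = c(mean = 0.5, sd = 0.1),
       tilt = c(mean = 0.5, sd = 0.15))
}

voice_knob_map <- function()
  data.frame(indicator = indicator_names(),
             knob = c("f0", "For1", "For2", "For3", "gain", "tilt",
                      "f0", "For1", "For2", "For3"),
             sign = c(1, 1, 1, 1, 1, 1, -1, -1, -1, -1))

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

generate_subject <- function(spec, labels, subject_seed) {
  with_seed(subject_seed, {
    pp <- cohort_params()
    eff <- spec$effects
    pos <- which(labels == 1)

    # --- face ---
    amp_base <- max(0.2, rnorm(1, pp$face_amp["mean"], pp$face_amp["sd"]))
    amp_face <- rep(amp_base, 68L)
    for (i in seq_len(10L)) {
      own <- (6L * (i - 1L) + 1L):(6L * i)
      if (labels[i] == 1) amp_face[own] <- amp_face[own] +
          eff[i, "face"] * pp$face_amp["sd"]
    }
    face <- generate_keypoint_motion("face", motion_amp = pmax(amp_face, 0.05),
                                     motion_freq = 0.8,
                                     noise_sd = spec$noise_sd[["face"]],
                                     duration = spec$face_duration,
                                     fps = spec$fps)

    # --- gait ---
    gait_base <- max(0.5, rnorm(1, pp$gait_amp["mean"], pp$gait_amp["sd"]))
    if (labels[10L] == 1) gait_base <- gait_base + eff[10L, "gait"] * pp$gait_amp["sd"]
    amp_gait <- rep(gait_base, 18L)
    for (i in seq_len(9L)) {
      if (labels[i] == 1) {
        own <- c(2L * i - 1L, 2L * i)
        amp_gait[own] <- amp_gait[own] + eff[i, "gait"] * pp$gait_amp["sd"]
      }
    }
    gait <- generate_keypoint_motion("gait", motion_amp = pmax(amp_gait, 0.05),
                                     motion_freq = 1,
                                     noise_sd = spec$noise_sd[["gait"]],
                                     duration = spec$gait_duration,
                                     fps = spec$fps)

    # --- voice ---
    knobs <- c(f0 = rnorm(1, pp$f0["mean"], pp$f0["sd"]),
               For1 = rnorm(1, pp$For1["mean"], pp$For1["sd"]),
               For2 = rnorm(1, pp$For2["mean"], pp$For2["sd"]),
               For3 = rnorm(1, pp$For3["mean"], pp$For3["sd"]),
               gain = rnorm(1, pp$gain["mean"], pp$gain["sd"]),
               tilt = rnorm(1, pp$tilt["mean"], pp$tilt["sd"]))
    km <- voice_knob_map()
    for (i in pos) {
      k <- km$knob[i]
      knobs[k] <- knobs[k] + km$sign[i] * eff[i, "voice"] * pp[[k]]["sd"]
    }
    f0 <- clamp(knobs[["f0"]], 80, 300)
    F1 <- clamp(knobs[["For1"]], 350, 1000)
    F2 <- max(clamp(knobs[["For2"]], 900, 2000), F1 + 150)
    F3 <- max(clamp(knobs[["For3"]], 2000, 3400), F2 + 300)
    gain <- clamp(knobs[["gain"]], 0.2, 0.8)
    tilt <- clamp(knobs[["tilt"]], 0, 0.95)
    voice <- unlist(lapply(seq_len(spec$voice_segments), function(s) {
      w <- synthesize_voice(clamp(f0 + rnorm(1, sd = 2), 80, 300),
                            c(F1, F2, F3), 1, spec$sample_rate,
                            noise_sd = spec$noise_sd[["voice"]])
      w <- c(w[1L], w[-1L] - tilt * w[-length(w)])  # spectral-tilt filter
      gain * w
    }))

    list(labels = labels, face = face, gait = gait, voice = voice,
         params = list(amp_face = amp_face, amp_gait = amp_gait, f0 = f0,
                       formants = c(F1, F2, F3), gain = gain, tilt = tilt))
  })
}

#' Generate a synthetic multimodal cohort
#'
#' Draws independent Bernoulli labels per indicator, shifts each subject's
#' generative parameters by the effects of their positive indicators, and
#' synthesizes the three streams per subject. With `dir` set, the cohort is
#' also written to disk (OpenPose-style JSON keypoints, float WAV audio,
#' labels CSV, manifest JSON); otherwise it stays in memory.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @return A `Cohort`: list with `spec`, `labels` (n x 10), `subjects`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  labels <- with_seed(spec$seed, {
    vapply(spec$prevalence, function(p) rbinom(spec$n_subjects, 1L, p),
           integer(spec$n_subjects))
  })
  labels <- matrix(labels, spec$n_subjects, 10L,
                   dimnames = list(NULL, indicator_names()))
  subjects <- lapply(seq_len(spec$n_subjects), function(i)
    generate_subject(spec, labels[i, ], child_seed(spec$seed, i)))
  cohort <- structure(list(spec = spec, labels = labels, subjects = subjects),
                      class = "Cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a cohort to disk
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  n <- spec$n_subjects
  ids <- sprintf("subj_%04d", seq_len(n))
  for (i in seq_len(n)) {
    s <- cohort$subjects[[i]]
    write_keypoints(s$face, file.path(dir, paste0(ids[i], "_face.json")))
    write_keypoints(s$gait, file.path(dir, paste0(ids[i], "_gait.json")))
    write_wav(s$voice, spec$sample_rate,
              file.path(dir, paste0(ids[i], "_voice.wav")), bits = 32L)
  }
  lab <- data.frame(subject_id = ids, cohort$labels)
  write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(
    generator = "mindfuse synthetic cohort (not real subject data)",
    n_subjects = n, seed = spec$seed, fps = spec$fps,
    sample_rate = spec$sample_rate, prevalence = as.list(spec$prevalence),
    effects = apply(spec$effects, 1L, as.list),
    noise_sd = as.list(spec$noise_sd),
    durations = list(face = spec$face_duration, gait = spec$gait_duration,
                     voice_segments = spec$voice_segments),
    subjects = ids)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory back into memory
#'
#' @param dir directory written by [write_cohort()].
#' @return A `Cohort` (spec fields restored from the manifest).
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop_mf("'%s' has no manifest.json; expected a cohort directory with %s",
            dir, "manifest.json, labels.csv, subj_*_{face,gait}.json, subj_*_voice.wav")
  m <- jsonlite::fromJSON(mpath)
  lab <- read.csv(file.path(dir, "labels.csv"))
  labels <- as.matrix(lab[, indicator_names()])
  subjects <- lapply(seq_along(m$subjects), function(i) {
    id <- m$subjects[i]
    wav <- read_wav(file.path(dir, paste0(id, "_voice.wav")))
    list(labels = labels[i, ],
         face = read_keypoints(file.path(dir, paste0(id, "_face.json")),
                               "face", m$fps),
         gait = read_keypoints(file.path(dir, paste0(id, "_gait.json")),
                               "gait", m$fps),
         voice = wav$samples)
  })
  spec <- cohort_spec(m$n_subjects, fps = m$fps, sample_rate = m$sample_rate,
                      seed = m$seed)
  structure(list(spec = spec, labels = labels, subjects = subjects),
            class = "Cohort")
}

#' Extract per-subject modality feature matrices from a cohort
#'
#' Runs the full feature pipeline on every subject: keypoint streams are
#' confidence-repaired, segmented (30 s face / 8 s gait) and converted to
#' displacement channels; voice is Wiener-denoised, cut into 1 s segments and
#' run through the 17-descriptor short-time analysis. Channel series are
#' concatenated across segments before the time-domain statistics.
#'
#' @param cohort a `Cohort`.
#' @param stats a [stat_set()].
#' @param conf_threshold keypoint confidence threshold.
#' @param ... passed to [extract_voice_features()].
#' @return A `CohortFeatures`: `subjects` (list of per-modality
#'   `ModalFeatureMatrix`), `labels`, `stat_set`.
#' @export
extract_cohort_features <- function(cohort, stats = stat_set(),
                                    conf_threshold = 0.1, ...) {
  stopifnot(inherits(cohort, "Cohort"))
  sr <- cohort$spec$sample_rate
  subjects <- lapply(cohort$subjects, function(s) {
    list(face = build_modal_feature_matrix(
           keypoint_channels_segmented(s$face, conf_threshold), stats),
         gait = build_modal_feature_matrix(
           keypoint_channels_segmented(s$gait, conf_threshold), stats),
         voice = build_modal_feature_matrix(
           voice_channels_segmented(s$voice, sr, ...), stats))
  })
  structure(list(subjects = subjects, labels = cohort$labels,
                 stat_set = stats),
            class = "CohortFeatures")
}

# Segment a keypoint stream and concatenate per-segment displacement channels.
keypoint_channels_segmented <- function(seq, conf_threshold = 0.1) {
  seq <- interpolate_missing(seq, conf_threshold)
  segs <- segment_sequence(seq)
  if (!length(segs)) segs <- list(seq)  # short stream: use as a single window
  per_seg <- lapply(segs, keypoint_channel_series)
  merge_channel_segments(per_seg)
}

# Denoise, cut into 1 s pieces, extract, concatenate the 17 voice channels.
voice_channels_segmented <- function(samples, sample_rate, ...) {
  den <- wiener_denoise(samples, sample_rate)
  segs <- segment_audio(den, sample_rate)
  if (!length(segs)) stop_mf("voice stream shorter than half a second")
  per_seg <- lapply(segs, function(sg) extract_voice_features(sg, ...)$channels)
  merge_channel_segments(per_seg)
}

merge_channel_segments <- function(per_seg) {
  if (length(per_seg) == 1L) return(per_seg[[1L]])
  lapply(seq_along(per_seg[[1L]]), function(ch) {
    tpl <- per_seg[[1L]][[ch]]
    channel_series(tpl$modality, tpl$index,
                   unlist(lapply(per_seg, function(p) p[[ch]]$values)),
                   valid = unlist(lapply(per_seg, function(p) p[[ch]]$valid)),
                   name = tpl$name,
                   x_axis = if (!is.null(tpl$x_axis))
                     unlist(lapply(per_seg, function(p) p[[ch]]$x_axis)),
                   y_axis = if (!is.null(tpl$y_axis))
                     unlist(lapply(per_seg, function(p) p[[ch]]$y_axis)))
  })
}
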