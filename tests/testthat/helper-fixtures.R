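# Fixture builders shared across the test files. Everything is generated in
# code; nothing is read from disk except through the package's own writers.

# A small deterministic keypoint sequence: points move on fixed circles.
fixture_keypoints <- function(modality = "face", n_frames = 50L, fps = 25,
                              conf = NULL) {
  p <- if (modality == "face") 68L else 18L
  tt <- seq_len(n_frames)
  x <- outer(tt, seq_len(p), function(t, j) 100 + j + 3 * sin(t / 5 + j))
  y <- outer(tt, seq_len(p), function(t, j) 200 + j + 3 * cos(t / 5 + j))
  if (is.null(conf)) conf <- matrix(0.9, n_frames, p)
  keypoint_sequence(x, y, conf, modality, fps)
}

# Voiced synthetic segment (1 s, source-filter, default parameters).
fixture_voiced_segment <- function(seed = 1, f0 = 120,
                                   formants = c(700, 1200, 2600),
                                   sr = 16000, noise_sd = 0.01) {
  w <- mindfuse:::with_seed(seed,
    synthesize_voice(f0, formants, 1, sr, noise_sd = noise_sd))
  audio_segment(w, sr)
}

# White noise through a cascade of two-pole resonators (planted formants,
# noise excitation) -- built independently of synthesize_voice's pulse train.
fixture_resonant_noise <- function(seed, formants = c(700, 1200, 2600),
                                   bw = 80, sr = 16000, dur = 1) {
  mindfuse:::with_seed(seed, {
    x <- rnorm(sr * dur)
    for (fq in formants) {
      r <- exp(-pi * bw / sr)
      th <- 2 * pi * fq / sr
      x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r^2),
                                    method = "recursive"))
    }
    0.9 * x / max(abs(x))
  })
}

# Channel list with known values for the statistics module.
fixture_channels <- function(modality = "gait", k = 3L, n = 40L, seed = 9) {
  mindfuse:::with_seed(seed, lapply(seq_len(k), function(i)
    channel_series(modality, i, rnorm(n, mean = i),
                   x_axis = rnorm(n), y_axis = rnorm(n))))
}

# Random ModalFeatureMatrix-shaped inputs for fusion tests.
fixture_modal_matrices <- function(seed = 4, stats = stat_set()) {
  mindfuse:::with_seed(seed, {
    mk <- function(mod, k) {
      m <- matrix(rnorm(k * length(stats), mean = 2), k, length(stats))
      colnames(m) <- as.character(stats)
      structure(m, modality = mod, stat_set = stats,
                class = c("ModalFeatureMatrix", "matrix"))
    }
    list(F = mk("face", 68L), V = mk("voice", 17L), G = mk("gait", 18L))
  })
}

# Small extracted cohort for evaluation tests (kept tiny for speed).
fixture_dataset <- function(n = 24L, effects = 3, seed = 11,
                            face_duration = 6, gait_duration = 4,
                            voice_segments = 1L) {
  spec <- cohort_spec(n, effects = effects, seed = seed,
                      face_duration = face_duration,
                      gait_duration = gait_duration,
                      voice_segments = voice_segments)
  suppressWarnings(extract_cohort_features(generate_cohort(spec)))
}

# Complementary-signal effects matrix used by the ablation tests: face
# carries indicators 1-4, voice 5-7, gait 8-10.
complementary_effects <- function(face = 2, voice = 3, gait = 2) {
  eff <- matrix(0, 10, 3,
                dimnames = list(indicator_names(), c("face", "voice", "gait")))
  eff[1:4, "face"] <- face
  eff[5:7, "voice"] <- voice
  eff[8:10, "gait"] <- gait
  eff
}
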