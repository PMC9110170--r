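#' Audio segments
#'
#' An `AudioSegment` is at most one second of mono waveform, the unit the
#' preprocessing stage produces and the per-frame voice descriptors consume.
#'
#' @param samples numeric amplitudes in `[-1, 1]` (finite).
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `AudioSegment` with `samples`, `sample_rate`,
#'   `duration` (seconds).
#' @export
audio_segment <- function(samples, sample_rate) {
  if (!is_scalar_num(sample_rate) || sample_rate <= 0)
    stop_mf("sample_rate must be positive")
  if (any(!is.finite(samples))) stop_mf("samples must be finite")
  dur <- length(samples) / sample_rate
  if (dur > 1 + 1e-9)
    stop_mf("AudioSegment must be at most 1 s (got %.3f s); use segment_audio()", dur)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 duration = dur),
            class = "AudioSegment")
}

#' Adaptive Wiener denoising
#'
#' Local-statistics Wiener filter: within a sliding window the local mean and
#' variance are estimated, the noise power is taken as the mean of the local
#' variances across the signal, and each sample is shrunk towards its local
#' mean in proportion to the estimated local SNR.
#'
#' @param samples waveform.
#' @param sample_rate sampling rate in Hz (kept for interface symmetry).
#' @param noise_window odd local window length in samples, at least 3
#'   (default 11).
#' @return Denoised waveform of the same length.
#' @export
wiener_denoise <- function(samples, sample_rate = NULL, noise_window = 11L) {
  if (length(samples) == 0L) stop_mf("empty input")
  if (!is_scalar_num(noise_window) || noise_window < 3)
    stop_mf("noise_window must be at least 3")
  w <- as.integer(noise_window)
  n <- length(samples)
  if (w > n) w <- if (n %% 2L == 1L) n else n - 1L
  if (w < 3L) return(samples)
  half <- w %/% 2L
  pad <- c(numeric(half), samples, numeric(half))
  kern <- rep(1 / w, w)
  m <- as.numeric(stats::filter(pad, kern, sides = 2))[(half + 1L):(half + n)]
  m2 <- as.numeric(stats::filter(pad^2, kern, sides = 2))[(half + 1L):(half + n)]
  v <- pmax(m2 - m^2, 0)
  noise <- mean(v)
  gain <- ifelse(v > noise, (v - noise) / v, 0)
  m + gain * (samples - m)
}

#' Cut a waveform into one-second segments
#'
#' Consecutive non-overlapping 1 s pieces; a trailing partial of at least
#' 0.5 s is kept, shorter remainders are dropped.
#'
#' @param samples waveform.
#' @param sample_rate sampling rate in Hz.
#' @return A list of [audio_segment()]s (possibly empty).
#' @export
segment_audio <- function(samples, sample_rate) {
  if (!is_scalar_num(sample_rate) || sample_rate <= 0)
    stop_mf("sample_rate must be positive")
  n <- length(samples)
  seg <- as.integer(round(sample_rate))
  n_full <- n %/% seg
  rem <- n - n_full * seg
  out <- lapply(seq_len(n_full), function(i)
    audio_segment(samples[(i - 1L) * seg + seq_len(seg)], sample_rate))
  if (rem >= seg / 2)
    out <- c(out, list(audio_segment(samples[(n_full * seg + 1L):n], sample_rate)))
  out
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

# samples -> matrix of frames (frame_len x n_frames), fixed hop, no padding.
frame_matrix <- function(x, frame_len, hop) {
  n_frames <- (length(x) - frame_len) %/% hop + 1L
  idx <- outer(seq_len(frame_len), (seq_len(n_frames) - 1L) * hop, `+`)
  matrix(x[idx], frame_len, n_frames)
}

#' Short-time framing
#'
#' Splits an audio segment into overlapping analysis frames. The frame count
#' is `floor((len - frame_len)/hop) + 1` in samples. Pre-emphasis, when
#' requested, is applied to the whole segment before framing (used on the
#' formant/MFCC paths only; the short-time energy path frames the raw signal).
#'
#' @param segment an [audio_segment()].
#' @param frame_len frame length in seconds (default 25 ms).
#' @param hop hop in seconds (default 10 ms).
#' @param window `"hamming"` or `"rect"`.
#' @param preemphasis first-order pre-emphasis coefficient (0 = off).
#' @return A `frame_len_samples x n_frames` matrix; attributes `sample_rate`,
#'   `hop_samples`.
#' @export
frame_signal <- function(segment, frame_len = 0.025, hop = 0.010,
                         window = c("hamming", "rect"), preemphasis = 0) {
  stopifnot(inherits(segment, "AudioSegment"))
  window <- match.arg(window)
  sr <- segment$sample_rate
  fl <- as.integer(round(frame_len * sr))
  hp <- as.integer(round(hop * sr))
  if (fl < 1L || hp < 1L) stop_mf("frame_len and hop must be at least one sample")
  x <- segment$samples
  if (length(x) < fl)
    stop_mf("segment (%d samples) shorter than one frame (%d samples)",
            length(x), fl)
  if (hp > fl) warn_mf("hop (%d) exceeds frame length (%d): frames leave gaps", hp, fl)
  if (preemphasis > 0) x <- c(x[1L], x[-1L] - preemphasis * x[-length(x)])
  frames <- frame_matrix(x, fl, hp)
  if (window == "hamming") frames <- frames * hamming_window(fl)
  structure(frames, sample_rate = sr, hop_samples = hp)
}

#' Short-time energy of one frame
#'
#' Sum of squared raw samples over the frame (no windowing).
#'
#' @param frame numeric frame.
#' @return Non-negative energy.
#' @export
short_time_energy <- function(frame) {
  if (length(frame) == 0L) stop_mf("empty frame")
  sum(frame^2)
}

# Real cepstra of zero-padded frame columns: IFFT of the decimal-log
# magnitude spectrum, clamped to 4 decades below each frame's spectral peak
# so that near-zero bins (window sidelobes) do not dominate the transform.
# The log makes the result amplitude-invariant beyond quefrency zero.
real_cepstrum <- function(frames, n_fft, dynamic_range = 4) {
  padded <- rbind(frames, matrix(0, n_fft - nrow(frames), ncol(frames)))
  logmag <- log10(abs(mvfft(padded)) + 1e-12)
  peak <- apply(logmag, 2L, max)
  logmag <- pmax(logmag, rep(peak - dynamic_range, each = nrow(logmag)))
  Re(mvfft(logmag, inverse = TRUE)) / n_fft
}

# Vectorized pitch over frame columns. Two voicing routes (D5):
#   1. cepstral peak in the quefrency band >= prominence threshold -- the
#      usual source/filter separation, needing >= 2 harmonics;
#   2. a single dominant spectral line: if the strongest spectral peak lies
#      in the pitch band and carries >= 50% of the frame power, the frame is
#      periodic by inspection (e.g. a pure sine) at the line frequency.
# Returns list(pitch, voiced).
pitch_from_frames <- function(frames, sample_rate, fmin, fmax, prominence) {
  q_lo <- as.integer(ceiling(sample_rate / fmax))
  q_hi <- as.integer(floor(sample_rate / fmin))
  n_fft <- 2^ceiling(log2(max(2L * nrow(frames), 2L * q_hi + 2L)))
  cep <- real_cepstrum(frames, n_fft)
  band <- cep[(q_lo + 1L):(q_hi + 1L), , drop = FALSE]  # +1: quefrency 0 is row 1
  peak_rel <- apply(band, 2L, which.max)
  peak_val <- band[cbind(peak_rel, seq_len(ncol(band)))]
  voiced <- peak_val >= prominence
  pitch <- ifelse(voiced, sample_rate / (q_lo + peak_rel - 1L), 0)

  padded <- rbind(frames, matrix(0, n_fft - nrow(frames), ncol(frames)))
  pow <- Mod(mvfft(padded))^2
  half <- pow[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  lobe <- as.integer(ceiling(4 * n_fft / nrow(frames)))
  for (j in which(!voiced)) {
    tot <- sum(half[, j])
    if (tot <= 0) next
    pk <- which.max(half[, j])
    f_pk <- (pk - 1L) * sample_rate / n_fft
    if (f_pk < fmin || f_pk > fmax) next
    rng <- max(1L, pk - lobe):min(nrow(half), pk + lobe)
    if (sum(half[rng, j]) / tot >= 0.5) {
      voiced[j] <- TRUE
      # parabolic interpolation of the log-power peak: bin-level quantization
      # (sr/n_fft) would otherwise dominate the estimate
      if (pk > 1L && pk < nrow(half)) {
        lp <- log(half[(pk - 1L):(pk + 1L), j] + 1e-300)
        denom <- lp[1L] - 2 * lp[2L] + lp[3L]
        delta <- if (denom < 0) 0.5 * (lp[1L] - lp[3L]) / denom else 0
        f_pk <- (pk - 1L + max(-0.5, min(0.5, delta))) * sample_rate / n_fft
      }
      pitch[j] <- f_pk
    }
  }
  list(pitch = pitch, voiced = voiced)
}

#' Cepstral pitch estimation
#'
#' Real-cepstrum peak picking: the log-magnitude spectrum separates the
#' glottal excitation from the vocal-tract filter, so a voiced frame shows a
#' cepstral peak at the pitch period. The peak is searched between
#' `sr/fmax` and `sr/fmin` samples of quefrency. The cepstral test needs at
#' least two harmonics; a frame whose spectrum is a single dominant line
#' inside the band (at least half the frame power at the strongest peak) is
#' periodic by inspection and voiced at the line frequency. Frames passing
#' neither test are unvoiced and return 0.
#'
#' @param frame numeric frame (apply a taper first for best results).
#' @param sample_rate Hz.
#' @param fmin,fmax pitch search band in Hz (default 50-500).
#' @param prominence voicing threshold on the cepstral peak (default 0.08).
#' @return Pitch in Hz, or 0 for unvoiced.
#' @export
estimate_pitch <- function(frame, sample_rate, fmin = 50, fmax = 500,
                           prominence = 0.08) {
  if (fmin <= 0 || fmax <= fmin || fmax > sample_rate / 2)
    stop_mf("need 0 < fmin < fmax <= sample_rate/2")
  if (length(frame) < 2 * sample_rate / fmin)
    stop_mf("frame too short (%d samples) for the %g Hz search floor (need %d)",
            length(frame), fmin, ceiling(2 * sample_rate / fmin))
  pitch_from_frames(matrix(frame, ncol = 1L), sample_rate, fmin, fmax,
                    prominence)$pitch
}

#' LPC-root formant estimation
#'
#' Fits an all-pole model by the autocorrelation method (Levinson-Durbin),
#' then takes the roots of the prediction polynomial. Roots with positive
#' imaginary part, bandwidth below 400 Hz and frequency inside
#' `[90, sr/2 - 50]` Hz qualify as formants; the lowest three are returned in
#' ascending order, with zeros filling missing slots.
#'
#' @param frame pre-emphasized, windowed frame.
#' @param sample_rate Hz.
#' @param lpc_order model order; default `2 + sample_rate/1000`.
#' @return Numeric `c(For1, For2, For3)`.
#' @export
estimate_formants <- function(frame, sample_rate,
                              lpc_order = round(2 + sample_rate / 1000)) {
  if (all(frame == 0)) stop_mf("all-zero frame: autocorrelation degenerate")
  out <- cpp_formants(matrix(frame, ncol = 1L), as.integer(lpc_order),
                      sample_rate, 400, 90, sample_rate / 2 - 50)
  as.numeric(out[, 1L])
}

# Mel scale per 2595*log10(1 + f/700) and its inverse.
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular Mel filterbank, n_mel x (n_fft/2 + 1), spanning 0..sr/2.
mel_filterbank <- function(sample_rate, n_fft, n_mel) {
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                         length.out = n_mel + 2L))
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    rise <- (bin_hz - lo) / (mid - lo)
    fall <- (hi - bin_hz) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(rise, fall))
  }
  fb
}

# Orthonormal DCT-II matrix, n_out x n_in, rows k = 1..n_out (AC terms only
# when drop_first), applied to log filterbank energies.
dct_matrix <- function(n_in, n_out) {
  k <- seq_len(n_out)
  m <- outer(k, seq_len(n_in) - 0.5, function(k, n) cos(pi * k * n / n_in))
  m * sqrt(2 / n_in)
}

mfcc_from_power <- function(power_bins, fb, dct_m, floor_val = 1e-10) {
  energies <- fb %*% power_bins
  dct_m %*% log(pmax(energies, floor_val))
}

#' Mel-frequency cepstral coefficients of one frame
#'
#' Power spectrum `|FFT(x)|^2 / N` of the zero-padded frame, triangular Mel
#' filterbank energies, natural log (floored at 1e-10), orthonormal DCT-II;
#' coefficients 1..`n_coeff` are returned (coefficient 0 is dropped).
#'
#' @param frame pre-emphasized, windowed frame; must not exceed `n_fft`.
#' @param sample_rate Hz.
#' @param n_fft FFT size (default 512).
#' @param n_mel number of Mel filters (default 26).
#' @param n_coeff number of coefficients kept (default 12).
#' @return Numeric vector of length `n_coeff`.
#' @export
compute_mfcc <- function(frame, sample_rate, n_fft = 512L, n_mel = 26L,
                         n_coeff = 12L) {
  if (length(frame) > n_fft)
    stop_mf("frame (%d samples) longer than n_fft (%d): resample explicitly",
            length(frame), n_fft)
  padded <- c(frame, numeric(n_fft - length(frame)))
  spec <- fft(padded)
  power <- (Mod(spec)^2 / n_fft)[seq_len(n_fft %/% 2L + 1L)]
  fb <- mel_filterbank(sample_rate, n_fft, n_mel)
  as.numeric(mfcc_from_power(matrix(power, ncol = 1L), fb,
                             dct_matrix(n_mel, n_coeff)))
}

voice_channel_names <- function(n_coeff = 12L)
  c("E", "PF", "For1", "For2", "For3", paste0("mfcc", seq_len(n_coeff)))

#' Extract the 17 per-frame voice descriptors from one segment
#'
#' Runs the full short-time analysis: energy on raw frames, cepstral pitch on
#' a dedicated 40 ms window (two periods at the 50 Hz search floor) sharing
#' the frame grid, LPC-root formants and MFCCs on pre-emphasized Hamming
#' frames. Results come back both as a per-frame table and as 17
#' [channel_series()] (`E, PF, For1..3, mfcc1..12`) for the statistics stage;
#' unvoiced frames are masked invalid on the pitch channel only.
#'
#' @param segment an [audio_segment()].
#' @param frame_len,hop framing in seconds (defaults 25 ms / 10 ms).
#' @param n_fft,n_mel,n_coeff MFCC parameters (defaults 512 / 26 / 12).
#' @param pitch_band pitch search band in Hz (default `c(50, 500)`).
#' @param preemphasis pre-emphasis for the spectral paths (default 0.97).
#' @param pitch_prominence voicing threshold (default 0.08).
#' @param lpc_order LPC order; default `2 + sample_rate/1000`.
#' @return A list: `features` (data.frame, one row per frame, columns
#'   `frame, E, PF, For1..3, mfcc1..12`) and `channels` (17 `ChannelSeries`).
#' @export
extract_voice_features <- function(segment, frame_len = 0.025, hop = 0.010,
                                   n_fft = 512L, n_mel = 26L, n_coeff = 12L,
                                   pitch_band = c(50, 500), preemphasis = 0.97,
                                   pitch_prominence = 0.08, lpc_order = NULL) {
  stopifnot(inherits(segment, "AudioSegment"))
  sr <- segment$sample_rate
  if (is.null(lpc_order)) lpc_order <- as.integer(round(2 + sr / 1000))
  raw <- frame_signal(segment, frame_len, hop, window = "rect")
  nf <- ncol(raw)
  hp <- attr(raw, "hop_samples")

  energy <- colSums(raw^2)

  # Pitch: 40 ms windows (>= 2 periods of the band floor) on the same frame
  # starts; tail windows are zero-padded so all channels share length nf.
  pitch_win <- as.integer(ceiling(2 * sr / pitch_band[1L]))
  xp <- c(segment$samples, numeric(max(0L, (nf - 1L) * hp + pitch_win -
                                          length(segment$samples))))
  pframes <- frame_matrix(xp, pitch_win, hp)[, seq_len(nf), drop = FALSE]
  pframes <- pframes * hamming_window(pitch_win)
  pres <- pitch_from_frames(pframes, sr, pitch_band[1L], pitch_band[2L],
                            pitch_prominence)

  spec_frames <- frame_signal(segment, frame_len, hop, window = "hamming",
                              preemphasis = preemphasis)
  if (nrow(spec_frames) > n_fft)
    stop_mf("frame length exceeds n_fft; enlarge n_fft or shorten frames")

  formants <- cpp_formants(spec_frames, as.integer(lpc_order), sr,
                           400, 90, sr / 2 - 50)

  padded <- rbind(spec_frames, matrix(0, n_fft - nrow(spec_frames), nf))
  power <- (Mod(mvfft(padded))^2 / n_fft)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  mfcc <- mfcc_from_power(power, mel_filterbank(sr, n_fft, n_mel),
                          dct_matrix(n_mel, n_coeff))

  feats <- data.frame(frame = seq_len(nf) - 1L, E = energy, PF = pres$pitch,
                      For1 = formants[1L, ], For2 = formants[2L, ],
                      For3 = formants[3L, ], t(mfcc))
  names(feats)[7:(6 + n_coeff)] <- paste0("mfcc", seq_len(n_coeff))

  vals <- rbind(energy, pres$pitch, formants, mfcc)
  nm <- voice_channel_names(n_coeff)
  channels <- lapply(seq_len(nrow(vals)), function(i) {
    valid <- if (nm[i] == "PF") pres$voiced else rep(TRUE, nf)
    channel_series("voice", i, vals[i, ], valid = valid, name = nm[i])
  })
  list(features = feats, channels = channels)
}
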