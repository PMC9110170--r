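test_that("wiener_denoise improves SNR on a noisy sine and passes silence through", {
  expect_identical(wiener_denoise(numeric(100)), numeric(100))
  expect_error(wiener_denoise(numeric(0)), "empty")
  expect_error(wiener_denoise(rnorm(50), noise_window = 1), "at least 3")

  sr <- 8000
  clean <- sin(2 * pi * 440 * (0:(sr - 1)) / sr)
  noisy <- mindfuse:::with_seed(3, clean + rnorm(sr, sd = sqrt(mean(clean^2) / 10^(5 / 10))))
  den <- wiener_denoise(noisy, sr)
  snr <- function(x) 10 * log10(mean(clean^2) / mean((x - clean)^2))
  expect_gt(snr(den), snr(noisy))
})

test_that("segment_audio cuts 1 s pieces with the half-second rule", {
  sr <- 1000
  expect_length(segment_audio(rnorm(10 * sr), sr), 10L)
  segs <- segment_audio(rnorm(3.5 * sr), sr)
  expect_length(segs, 4L)
  expect_equal(segs[[4]]$duration, 0.5)
  expect_length(segment_audio(rnorm(0.3 * sr), sr), 0L)
  # sample conservation up to the dropped partial
  segs <- segment_audio(rnorm(2.2 * sr), sr)
  expect_equal(sum(vapply(segs, function(s) length(s$samples), 0L)), 2L * sr)
})

test_that("frame_signal yields floor((len-flen)/hop)+1 frames", {
  seg <- audio_segment(rnorm(16000), 16000)
  fr <- frame_signal(seg, 0.025, 0.010, window = "rect")
  expect_identical(ncol(fr), 98L)
  expect_identical(nrow(fr), 400L)
  # frame_len = segment length -> exactly one frame
  seg2 <- audio_segment(rnorm(800), 16000)
  expect_identical(ncol(frame_signal(seg2, 0.05, 0.01, window = "rect")), 1L)
  expect_error(frame_signal(audio_segment(rnorm(100), 16000), 0.025, 0.01),
               "shorter than one frame")
  expect_warning(frame_signal(seg, 0.010, 0.020), "gaps")
})

test_that("short_time_energy is the plain sum of squares with its invariances", {
  expect_equal(short_time_energy(c(1, 1, 1, 1)), 4)
  expect_equal(short_time_energy(numeric(5)), 0)
  expect_equal(short_time_energy(c(3, 4)), 25)
  expect_error(short_time_energy(numeric(0)), "empty")
  fr <- mindfuse:::with_seed(2, rnorm(128))
  expect_equal(short_time_energy(-fr), short_time_energy(fr))
  expect_equal(short_time_energy(2.5 * fr), 2.5^2 * short_time_energy(fr))
})

test_that("estimate_pitch recovers planted periodicity and rejects noise", {
  sr <- 16000
  hw <- mindfuse:::hamming_window(640L)

  # glottal pulse train through an all-pole tract at 120 Hz; oracle is the
  # autocorrelation peak of the known excitation (period = round(sr/f0))
  seg <- fixture_voiced_segment(seed = 5)
  f_true <- sr / round(sr / 120)
  fr <- seg$samples[2001:2640] * hw
  expect_lt(abs(estimate_pitch(fr, sr) - f_true), 3)

  # pure sine: closed-form period
  sine <- sin(2 * pi * 200 * (0:799) / sr)
  expect_lt(abs(estimate_pitch(sine[1:640] * hw, sr) - 200), 3)

  # white noise is unvoiced
  noise <- mindfuse:::with_seed(8, rnorm(640))
  expect_identical(estimate_pitch(noise * hw, sr), 0)

  # amplitude scaling and polarity invariance
  expect_equal(estimate_pitch(0.01 * fr, sr), estimate_pitch(fr, sr))
  expect_equal(estimate_pitch(-fr, sr), estimate_pitch(fr, sr))

  # too-short frame for the band floor
  expect_error(estimate_pitch(rnorm(200), sr), "too short")
})

test_that("estimate_formants recovers planted resonances", {
  sr <- 16000
  # planted 700/1200/2600 Hz resonances excited by white noise, 10 seeds,
  # median over 50 frames within +-50 Hz per formant
  errs <- sapply(1:10, function(s) {
    x <- fixture_resonant_noise(s)
    fr <- frame_signal(audio_segment(x, sr), window = "hamming",
                       preemphasis = 0.97)
    fo <- sapply(1:50, function(i) estimate_formants(fr[, i], sr))
    apply(fo, 1, median) - c(700, 1200, 2600)
  })
  expect_lt(max(abs(errs)), 50)

  # pure sine: fewer than 3 qualifying roots -> zero-filled slots
  sine <- sin(2 * pi * 500 * (0:399) / sr)
  fo <- estimate_formants(sine * mindfuse:::hamming_window(400L), sr)
  expect_true(any(fo == 0))

  # ordering invariant among nonzero slots
  nz <- fo[fo > 0]
  expect_false(is.unsorted(nz, strictly = TRUE))
  expect_error(estimate_formants(numeric(400), sr), "all-zero")
})

test_that("compute_mfcc matches the brute-force oracle", {
  sr <- 16000
  seg <- fixture_voiced_segment(seed = 7)
  frames <- frame_signal(seg, window = "hamming", preemphasis = 0.97)
  idx <- mindfuse:::with_seed(10, sample(ncol(frames), 100L, replace = TRUE))
  for (i in idx) {
    got <- compute_mfcc(frames[, i], sr)
    expect_equal(got, oracle_mfcc(frames[, i], sr), tolerance = 1e-6)
  }
  expect_length(compute_mfcc(frames[, 1], sr), 12L)
  # all-zero frame: constant log-floor -> every AC coefficient is 0
  expect_equal(compute_mfcc(numeric(400), sr), numeric(12))
  expect_error(compute_mfcc(rnorm(600), sr), "longer than n_fft")
})

test_that("extract_voice_features assembles 17 aligned channels", {
  seg <- fixture_voiced_segment(seed = 3)
  out <- extract_voice_features(seg)
  expect_length(out$channels, 17L)
  lens <- vapply(out$channels, function(ch) length(ch$values), 0L)
  expect_true(all(lens == 98L))
  expect_identical(vapply(out$channels, `[[`, "", "name"),
                   c("E", "PF", "For1", "For2", "For3",
                     paste0("mfcc", 1:12)))
  expect_identical(nrow(out$features), 98L)

  # unvoiced-only segment: pitch channel fully masked, matrix row becomes
  # zeros with a warning downstream
  noise_seg <- audio_segment(mindfuse:::with_seed(4, rnorm(16000, sd = 0.1)),
                             16000)
  nout <- extract_voice_features(noise_seg)
  pf <- nout$channels[[2]]
  expect_true(all(!pf$valid))
  expect_warning(m <- build_modal_feature_matrix(nout$channels), "PF")
  expect_equal(unname(unclass(m)["PF", ]), numeric(4))
})
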