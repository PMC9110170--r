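# Naive recomputation oracle for the moment statistics.
oracle_stats <- function(v, stats) {
  n <- length(v); m <- sum(v) / n
  s2 <- sum((v - m)^2) / (n - 1)
  s <- sqrt(s2)
  sk <- if (s2 == 0) 0 else n / ((n - 1) * (n - 2)) * sum(((v - m) / s)^3)
  ku <- if (s2 == 0) 0 else
    n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(((v - m) / s)^4) -
      3 * (n - 1)^2 / ((n - 2) * (n - 3))
  vals <- c(sum = sum(v), mean = m, min = min(v), max = max(v),
            variance = s2, std = s, skewness = sk, kurtosis = ku)
  vals[stats]
}

test_that("channel_statistics computes the named statistics in order", {
  ch <- channel_series("gait", 1, c(1, 2, 3, 4))
  got <- channel_statistics(ch, stat_set(c("sum", "mean", "min", "max")))
  expect_equal(unname(got), c(10, 2.5, 1, 4))

  expect_equal(unname(channel_statistics(
    channel_series("gait", 1, c(1, 2, 3, 4, 5)), stat_set("variance"))), 2.5)

  # constant series: zero variance, skewness/kurtosis 0 by convention
  got <- channel_statistics(channel_series("gait", 1, rep(7, 10)),
                            stat_set(c("variance", "skewness", "kurtosis")))
  expect_equal(unname(got), c(0, 0, 0))

  # matches the naive oracle on random series for the full set
  full <- stat_set(setdiff(mindfuse:::all_stats(), "axis_correlation"))
  for (s in 1:5) {
    v <- mindfuse:::with_seed(s, rexp(30))
    got <- channel_statistics(channel_series("voice", 1, v), full)
    expect_equal(got, oracle_stats(v, as.character(full)), tolerance = 1e-12)
  }

  # invalid points are excluded; fewer than 2 valid -> error
  ch <- channel_series("voice", 2, c(5, 0, 0, 9),
                       valid = c(TRUE, FALSE, FALSE, TRUE), name = "PF")
  expect_equal(unname(channel_statistics(ch, stat_set("mean"))), 7)
  ch1 <- channel_series("voice", 2, c(5, 1), valid = c(TRUE, FALSE))
  expect_error(channel_statistics(ch1), "valid points")
})

test_that("statistics transform correctly under shift and scale", {
  v <- mindfuse:::with_seed(21, rnorm(50))
  ch <- function(x) channel_series("face", 1, x)
  full <- stat_set(setdiff(mindfuse:::all_stats(), "axis_correlation"))
  base <- channel_statistics(ch(v), full)
  shifted <- channel_statistics(ch(v + 10), full)
  scaled <- channel_statistics(ch(3 * v), full)
  expect_equal(shifted[["mean"]], base[["mean"]] + 10)
  expect_equal(shifted[["min"]], base[["min"]] + 10)
  expect_equal(shifted[["max"]], base[["max"]] + 10)
  for (s in c("variance", "std", "skewness", "kurtosis"))
    expect_equal(shifted[[s]], base[[s]], tolerance = 1e-9)
  expect_equal(scaled[["variance"]], 9 * base[["variance"]])
  expect_equal(scaled[["std"]], 3 * base[["std"]])
  expect_equal(scaled[["skewness"]], base[["skewness"]], tolerance = 1e-9)
})

test_that("axis_correlation handles perfect, inverse and degenerate cases", {
  x <- 1:10
  expect_equal(axis_correlation(x, x), 1)
  expect_equal(axis_correlation(x, -x), -1)
  expect_equal(axis_correlation(rep(1, 10), x), 0)
  expect_error(axis_correlation(1:4, 1:5), "mismatch")
  # voice channels (no axis pair) report 0 when the statistic is requested
  ch <- channel_series("voice", 1, rnorm(10), name = "E")
  got <- channel_statistics(ch, stat_set(c("mean", "axis_correlation")))
  expect_equal(unname(got[["axis_correlation"]]), 0)
})

test_that("build_modal_feature_matrix has the documented shapes", {
  seq <- fixture_keypoints("face", n_frames = 40L)
  m <- build_modal_feature_matrix(keypoint_channel_series(seq))
  expect_equal(dim(m), c(68L, 4L))
  expect_true(all(is.finite(m)))
  expect_identical(attr(m, "modality"), "face")

  out <- extract_voice_features(fixture_voiced_segment(seed = 2))
  mv <- build_modal_feature_matrix(out$channels)
  expect_equal(dim(mv), c(17L, 4L))

  # arbitrary StatSet drives the column count
  m9 <- build_modal_feature_matrix(fixture_channels(k = 5L),
                                   stat_set(mindfuse:::all_stats()))
  expect_equal(dim(m9), c(5L, 9L))

  expect_error(build_modal_feature_matrix(list()), "empty")
  mixed <- c(fixture_channels("gait", 1L), fixture_channels("face", 1L))
  expect_error(build_modal_feature_matrix(mixed), "mixed")
})

test_that("feature matrix CSV round-trip preserves values", {
  m <- build_modal_feature_matrix(fixture_channels(k = 4L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(m, path)
  back <- read_feature_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_identical(attr(back, "modality"), "gait")
})
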