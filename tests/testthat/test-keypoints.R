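test_that("read_keypoints round-trips both dialects and validates point counts", {
  seq <- fixture_keypoints("face", n_frames = 10L)
  for (fmt in c("json", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_keypoints(seq, path, fmt)
    back <- read_keypoints(path, "face", fps = 25)
    expect_equal(back$x, seq$x, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(back$y, seq$y, tolerance = 1e-6, ignore_attr = TRUE)
    expect_identical(back$points_per_frame, 68L)
  }

  gait <- fixture_keypoints("gait", n_frames = 5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_keypoints(gait, path)
  expect_identical(read_keypoints(path, "gait", 25)$points_per_frame, 18L)
  # wrong modality for the point count -> format error naming the frame
  expect_error(read_keypoints(path, "face", 25), "frame 1")
  expect_error(read_keypoints("no/such/file.json", "face", 25), "cannot read")
})

test_that("keypoint_sequence enforces its invariants", {
  m <- matrix(1, 4, 17)
  expect_error(keypoint_sequence(m, m, m, "gait", 25), "18 points")
  m18 <- matrix(1, 4, 18)
  expect_error(keypoint_sequence(m18, m18, matrix(2, 4, 18), "gait", 25),
               "confidences")
  expect_error(keypoint_sequence(m18, m18, matrix(0.5, 4, 18), "gait", 0),
               "fps")
})

test_that("segment_sequence applies the half-duration rule", {
  # 60 s face -> exactly two 30 s segments
  segs <- segment_sequence(fixture_keypoints("face", n_frames = 1500L))
  expect_length(segs, 2L)
  expect_true(all(vapply(segs, length, 0L) == 750L))

  # 20 s gait -> two full 8 s segments plus a kept 4 s partial
  segs <- segment_sequence(fixture_keypoints("gait", n_frames = 500L))
  expect_length(segs, 3L)
  expect_equal(vapply(segs, length, 0L), c(200L, 200L, 100L))

  # 10 s face -> below half a segment: empty with a warning
  expect_warning(segs <- segment_sequence(fixture_keypoints("face", 250L)),
                 "shorter than half")
  expect_length(segs, 0L)

  # frame conservation: totals never exceed the input
  for (n in c(750L, 1100L, 1875L)) {
    segs <- segment_sequence(fixture_keypoints("face", n))
    expect_lte(sum(vapply(segs, length, 0L)), n)
  }
})

test_that("interpolate_missing repairs low-confidence points linearly", {
  seq <- fixture_keypoints("gait", n_frames = 5L)
  seq$x[, 1] <- c(10, 10, 999, 12, 12)  # frame 3 is junk
  seq$conf[3, 1] <- 0.01
  out <- interpolate_missing(seq, 0.1)
  expect_equal(out$x[3, 1], 11)          # midpoint of 10 and 12
  expect_equal(out$x[, 2], seq$x[, 2])   # untouched channels identical

  # leading gap held at nearest valid value
  seq2 <- fixture_keypoints("gait", n_frames = 4L)
  seq2$conf[1, 3] <- 0
  seq2$x[1, 3] <- -1
  out2 <- interpolate_missing(seq2)
  expect_equal(out2$x[1, 3], seq2$x[2, 3])

  # identity when nothing is below threshold
  clean <- fixture_keypoints("gait", n_frames = 6L)
  expect_equal(interpolate_missing(clean)$x, clean$x)

  # a point invalid everywhere is unrecoverable
  seq3 <- fixture_keypoints("gait", n_frames = 4L)
  seq3$conf[, 5] <- 0
  expect_error(interpolate_missing(seq3), "unrecoverable")
})

test_that("keypoint_channel_series is the displacement from the temporal mean", {
  # static point -> all-zero series; 68 channels for a face sequence
  p <- 68L
  x <- matrix(5, 10, p); y <- matrix(5, 10, p)
  seq <- keypoint_sequence(x, y, matrix(1, 10, p), "face", 25)
  chans <- keypoint_channel_series(seq)
  expect_length(chans, 68L)
  expect_true(all(abs(chans[[1]]$values) < 1e-12))

  # alternating (0,0)/(2,0) -> mean (1,0), displacement 1 everywhere
  x2 <- matrix(rep(c(0, 2), 5), 10, 18)
  seq2 <- keypoint_sequence(x2, matrix(0, 10, 18), matrix(1, 10, 18),
                            "gait", 25)
  expect_equal(keypoint_channel_series(seq2)[[4]]$values, rep(1, 10))

  expect_error(keypoint_channel_series(
    keypoint_sequence(matrix(1, 1, 18), matrix(1, 1, 18),
                      matrix(1, 1, 18), "gait", 25)), "2 frames")
})

test_that("channel series are translation-invariant", {
  seq <- fixture_keypoints("gait", n_frames = 30L)
  shifted <- keypoint_sequence(seq$x + 123.4, seq$y - 77.7, seq$conf,
                               "gait", seq$fps)
  a <- keypoint_channel_series(seq)
  b <- keypoint_channel_series(shifted)
  for (i in c(1L, 9L, 18L))
    expect_equal(a[[i]]$values, b[[i]]$values, tolerance = 1e-9)
})
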