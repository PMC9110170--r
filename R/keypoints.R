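#' Keypoint sequences
#'
#' A `KeypointSequence` holds one subject's landmark stream for one modality in
#' the OpenPose output convention: 68 facial landmarks or 18 body joints per
#' frame, each an `(x, y, confidence)` triple in pixel coordinates (origin
#' top-left), sampled at a fixed frame rate.
#'
#' @param x,y,conf numeric matrices, frames x points. `conf` entries must lie
#'   in `[0, 1]`.
#' @param modality `"face"` (68 points) or `"gait"` (18 points).
#' @param fps frames per second, positive.
#' @return An object of class `KeypointSequence` with elements `x`, `y`,
#'   `conf`, `modality`, `fps`, `points_per_frame`.
#' @export
keypoint_sequence <- function(x, y, conf, modality = c("face", "gait"), fps) {
  modality <- match.arg(modality)
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(conf)))
    stop_mf("x, y and conf must have identical dimensions")
  expected <- points_for_modality(modality)
  if (ncol(x) != expected)
    stop_mf("modality '%s' requires %d points per frame, got %d",
            modality, expected, ncol(x))
  if (!is_scalar_num(fps) || fps <= 0) stop_mf("fps must be a positive number")
  if (any(!is.finite(conf)) || any(conf < 0) || any(conf > 1))
    stop_mf("confidences must be finite and in [0, 1]")
  structure(
    list(x = x, y = y, conf = conf, modality = modality, fps = fps,
         points_per_frame = expected),
    class = "KeypointSequence")
}

points_for_modality <- function(modality) {
  switch(modality, face = 68L, gait = 18L,
         stop_mf("unknown modality '%s'", modality))
}

#' @export
print.KeypointSequence <- function(x, ...) {
  cat(sprintf("KeypointSequence: %s, %d frames x %d points @ %.3g fps (%.2f s)\n",
              x$modality, nrow(x$x), x$points_per_frame, x$fps,
              nrow(x$x) / x$fps))
  invisible(x)
}

#' @export
length.KeypointSequence <- function(x) nrow(x$x)

#' Read a keypoint stream
#'
#' Accepts either OpenPose-style JSON (an array of per-frame objects, each
#' `{"people":[{"pose_keypoints_2d":[x1,y1,c1,...]}]}`, optionally wrapped in
#' an object under a `frames` key) or a long-format CSV with columns
#' `frame, point, x, y, confidence`. The point count per frame is validated
#' against the declared modality (68 for face, 18 for gait).
#'
#' @param path file path.
#' @param modality `"face"` or `"gait"`.
#' @param fps frame rate of the recording (not stored in either format).
#' @return A [keypoint_sequence()].
#' @export
read_keypoints <- function(path, modality = c("face", "gait"), fps) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop_mf("cannot read keypoint file '%s'", path)
  expected <- points_for_modality(modality)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.null(doc$frames)) doc <- doc$frames
    if (length(doc) == 0L) stop_mf("'%s' contains no frames", path)
    triplets <- lapply(seq_along(doc), function(i) {
      fr <- doc[[i]]
      kp <- fr$people[[1]]$pose_keypoints_2d
      if (is.null(kp)) stop_mf("frame %d of '%s' has no pose_keypoints_2d", i, path)
      kp <- as.numeric(unlist(kp))
      if (length(kp) != 3L * expected)
        stop_mf("frame %d of '%s' has %d points, expected %d for modality '%s'",
                i, path, length(kp) %/% 3L, expected, modality)
      kp
    })
    flat <- do.call(rbind, triplets)
    idx <- seq_len(expected)
    keypoint_sequence(flat[, 3L * idx - 2L, drop = FALSE],
                      flat[, 3L * idx - 1L, drop = FALSE],
                      flat[, 3L * idx, drop = FALSE],
                      modality, fps)
  } else {
    df <- read.csv(path)
    need <- c("frame", "point", "x", "y", "confidence")
    if (!all(need %in% names(df)))
      stop_mf("'%s' must have columns %s", path, paste(need, collapse = ", "))
    frames <- sort(unique(df$frame))
    counts <- table(df$frame)
    bad <- names(counts)[counts != expected]
    if (length(bad))
      stop_mf("frame %s of '%s' has %d points, expected %d for modality '%s'",
              bad[1], path, counts[[bad[1]]], expected, modality)
    df <- df[order(df$frame, df$point), ]
    n <- length(frames)
    keypoint_sequence(matrix(df$x, n, expected, byrow = TRUE),
                      matrix(df$y, n, expected, byrow = TRUE),
                      matrix(df$confidence, n, expected, byrow = TRUE),
                      modality, fps)
  }
}

#' Write a keypoint stream (fixture writer)
#'
#' Emits the same two dialects [read_keypoints()] accepts, so the round trip is
#' the identity on coordinates.
#'
#' @param seq a [keypoint_sequence()].
#' @param path output path.
#' @param format `"json"` (OpenPose-style) or `"csv"` (long format).
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(seq, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "KeypointSequence"))
  n <- nrow(seq$x); p <- seq$points_per_frame
  if (format == "json") {
    frames <- lapply(seq_len(n), function(i) {
      kp <- as.vector(rbind(seq$x[i, ], seq$y[i, ], seq$conf[i, ]))
      list(people = list(list(pose_keypoints_2d = kp)))
    })
    jsonlite::write_json(frames, path, auto_unbox = TRUE, digits = 8)
  } else {
    df <- data.frame(
      frame = rep(seq_len(n) - 1L, each = p),
      point = rep(seq_len(p) - 1L, times = n),
      x = as.vector(t(seq$x)), y = as.vector(t(seq$y)),
      confidence = as.vector(t(seq$conf)))
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

subset_frames <- function(seq, idx) {
  keypoint_sequence(seq$x[idx, , drop = FALSE], seq$y[idx, , drop = FALSE],
                    seq$conf[idx, , drop = FALSE], seq$modality, seq$fps)
}

#' Split a keypoint stream into fixed-duration segments
#'
#' Face streams are cut into non-overlapping 30 s segments and gait streams
#' into 8 s segments. A trailing partial segment is kept when it is at least
#' half the target duration and dropped otherwise; a stream shorter than half
#' a segment yields an empty list with a warning.
#'
#' @param seq a [keypoint_sequence()].
#' @return A list of `KeypointSequence` segments.
#' @export
segment_sequence <- function(seq) {
  stopifnot(inherits(seq, "KeypointSequence"))
  target_s <- switch(seq$modality, face = 30, gait = 8)
  seg_len <- round(target_s * seq$fps)
  n <- nrow(seq$x)
  n_full <- n %/% seg_len
  rem <- n - n_full * seg_len
  if (n_full == 0L && rem < seg_len / 2) {
    warn_mf("%s sequence of %.2f s is shorter than half a %g s segment; no segments",
            seq$modality, n / seq$fps, target_s)
    return(list())
  }
  starts <- seq_len(n_full) * seg_len - seg_len + 1L
  segs <- lapply(starts, function(s) subset_frames(seq, s:(s + seg_len - 1L)))
  if (rem >= seg_len / 2)
    segs <- c(segs, list(subset_frames(seq, (n_full * seg_len + 1L):n)))
  segs
}

#' Repair low-confidence keypoints by temporal interpolation
#'
#' Points whose confidence falls below `conf_threshold` are replaced by linear
#' interpolation along time, per coordinate; leading/trailing gaps are held at
#' the nearest valid value. Interpolated points get confidence equal to the
#' threshold so they count as valid downstream.
#'
#' @param seq a [keypoint_sequence()].
#' @param conf_threshold confidence cutoff in `[0, 1]`, default `0.1`.
#' @return A repaired `KeypointSequence`.
#' @export
interpolate_missing <- function(seq, conf_threshold = 0.1) {
  stopifnot(inherits(seq, "KeypointSequence"))
  if (!is_scalar_num(conf_threshold) || conf_threshold < 0 || conf_threshold > 1)
    stop_mf("conf_threshold must be in [0, 1]")
  n <- nrow(seq$x)
  t_all <- seq_len(n)
  x <- seq$x; y <- seq$y; conf <- seq$conf
  for (p in seq_len(ncol(x))) {
    bad <- conf[, p] < conf_threshold
    if (!any(bad)) next
    if (all(bad))
      stop_mf("point %d has confidence below %.3g in every frame; channel unrecoverable",
              p, conf_threshold)
    ok <- !bad
    x[bad, p] <- approx(t_all[ok], x[ok, p], t_all[bad], rule = 2)$y
    y[bad, p] <- approx(t_all[ok], y[ok, p], t_all[bad], rule = 2)$y
    conf[bad, p] <- conf_threshold
  }
  keypoint_sequence(x, y, conf, seq$modality, seq$fps)
}

#' One scalar channel of a feature stream
#'
#' Internal container bridging raw streams to the time-domain statistics:
#' a scalar series with a validity mask, plus (for keypoint channels) the raw
#' x/y axis series used by the axis-correlation statistic.
#'
#' @param modality `"face"`, `"gait"` or `"voice"`.
#' @param index channel index within the modality.
#' @param values numeric series.
#' @param valid logical mask, same length as `values`.
#' @param name channel label.
#' @param x_axis,y_axis optional per-axis series (keypoint channels only).
#' @return An object of class `ChannelSeries`.
#' @export
channel_series <- function(modality, index, values, valid = NULL, name = NULL,
                           x_axis = NULL, y_axis = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  if (length(valid) != length(values))
    stop_mf("values and valid mask lengths differ (%d vs %d)",
            length(values), length(valid))
  if (any(!is.finite(values[valid])))
    stop_mf("non-finite values where valid_mask is true (channel %s:%d)",
            modality, index)
  structure(
    list(modality = modality, index = as.integer(index),
         name = if (is.null(name)) sprintf("%s_%02d", modality, index) else name,
         values = as.numeric(values), valid = as.logical(valid),
         x_axis = x_axis, y_axis = y_axis),
    class = "ChannelSeries")
}

#' Convert a keypoint sequence to per-point motion channels
#'
#' Each keypoint becomes one scalar channel: the Euclidean distance of the
#' point from its own temporal mean position (a motion-magnitude series).
#' This makes the channels translation-invariant and yields exactly one
#' channel per landmark (68 face + 18 gait), so the fused feature has
#' 68+18+17 = 103 channel rows. The raw x/y series are retained on each
#' channel for the axis-correlation statistic.
#'
#' @param seq a validated/interpolated [keypoint_sequence()].
#' @return A list of [channel_series()], one per keypoint.
#' @export
keypoint_channel_series <- function(seq) {
  stopifnot(inherits(seq, "KeypointSequence"))
  if (nrow(seq$x) < 2L) stop_mf("need at least 2 frames for channel series")
  mx <- colMeans(seq$x); my <- colMeans(seq$y)
  dx <- sweep(seq$x, 2L, mx); dy <- sweep(seq$y, 2L, my)
  disp <- sqrt(dx^2 + dy^2)
  lapply(seq_len(ncol(disp)), function(p)
    channel_series(seq$modality, p, disp[, p],
                   x_axis = seq$x[, p], y_axis = seq$y[, p]))
}
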