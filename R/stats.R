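#' Time-domain statistic sets
#'
#' The nine supported per-channel statistics, in their fixed canonical order:
#' arithmetic sum, mean, minimum, maximum, variance, standard deviation,
#' skewness, kurtosis, and the correlation coefficient between the two axes
#' of a keypoint channel. The default set is the four-statistic subset
#' `{mean, std, skewness, kurtosis}`, which makes the fused feature matrix
#' 103 x 4.
#'
#' @param stats character vector naming a subset of the nine statistics.
#' @return A `StatSet`: the validated names in canonical order.
#' @export
stat_set <- function(stats = c("mean", "std", "skewness", "kurtosis")) {
  all <- all_stats()
  stats <- unique(stats)
  bad <- setdiff(stats, all)
  if (length(bad)) stop_mf("unknown statistics: %s", paste(bad, collapse = ", "))
  if (!length(stats)) stop_mf("StatSet must be non-empty")
  structure(all[all %in% stats], class = "StatSet")
}

all_stats <- function()
  c("sum", "mean", "min", "max", "variance", "std", "skewness", "kurtosis",
    "axis_correlation")

# Sample (n-1) variance, adjusted Fisher-Pearson skewness, excess kurtosis;
# zero-variance series get skewness = kurtosis = 0 by convention.
moments_stats <- function(v) {
  n <- length(v)
  m <- mean(v)
  s2 <- var(v)
  s <- sqrt(s2)
  if (s2 <= 0 || n < 3) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- n / ((n - 1) * (n - 2)) * sum(((v - m) / s)^3)
    kurt <- if (n < 4) 0 else {
      n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(((v - m) / s)^4) -
        3 * (n - 1)^2 / ((n - 2) * (n - 3))
    }
  }
  c(sum = sum(v), mean = m, min = min(v), max = max(v), variance = s2,
    std = s, skewness = skew, kurtosis = kurt)
}

#' Pearson correlation between the two axes of a keypoint channel
#'
#' Returns 0 by convention when either axis is constant, and 0 for channels
#' that have no axis pair (voice descriptors).
#'
#' @param x_series,y_series equal-length numeric series.
#' @return Correlation in `[-1, 1]`.
#' @export
axis_correlation <- function(x_series, y_series) {
  if (length(x_series) != length(y_series))
    stop_mf("axis series length mismatch (%d vs %d)",
            length(x_series), length(y_series))
  if (length(x_series) < 2L) stop_mf("need at least 2 points")
  if (sd(x_series) == 0 || sd(y_series) == 0) return(0)
  cor(x_series, y_series)
}

#' Time-domain statistics of one channel
#'
#' Computes the requested statistics over the valid points of the series, in
#' StatSet order. Conventions: sample (n-1) variance/std, adjusted
#' Fisher-Pearson skewness, excess kurtosis (normal data -> 0), zero-variance
#' series -> skewness = kurtosis = 0. `axis_correlation` uses the channel's
#' retained x/y axis series and is 0 for channels without one.
#'
#' @param series a [channel_series()].
#' @param stats a [stat_set()].
#' @return Named numeric vector, one entry per statistic.
#' @export
channel_statistics <- function(series, stats = stat_set()) {
  stopifnot(inherits(series, "ChannelSeries"))
  if (!inherits(stats, "StatSet")) stats <- stat_set(stats)
  v <- series$values[series$valid]
  if (length(v) < 2L)
    stop_mf("channel %s has %d valid points; need at least 2",
            series$name, length(v))
  base <- moments_stats(v)
  out <- vapply(stats, function(s) {
    if (s == "axis_correlation") {
      if (is.null(series$x_axis)) 0
      else axis_correlation(series$x_axis[series$valid],
                            series$y_axis[series$valid])
    } else base[[s]]
  }, numeric(1))
  names(out) <- stats
  out
}

#' Assemble a per-modality feature matrix
#'
#' One row per channel (in channel order), one column per statistic. Under
#' defaults this is 68 x 4 for face, 17 x 4 for voice and 18 x 4 for gait. A
#' channel with fewer than 2 valid points (e.g. a fully unvoiced pitch
#' channel) yields a zero row with a warning rather than an error, so
#' degenerate segments keep the matrix shape.
#'
#' @param channels list of [channel_series()] from one modality.
#' @param stats a [stat_set()].
#' @return A `ModalFeatureMatrix`: numeric matrix with attributes `modality`,
#'   `stat_set`, and rownames = channel names.
#' @export
build_modal_feature_matrix <- function(channels, stats = stat_set()) {
  if (!length(channels)) stop_mf("empty channel list")
  if (!inherits(stats, "StatSet")) stats <- stat_set(stats)
  mods <- unique(vapply(channels, `[[`, "", "modality"))
  if (length(mods) != 1L)
    stop_mf("mixed modalities in channel list: %s", paste(mods, collapse = ", "))
  rows <- lapply(channels, function(ch) {
    tryCatch(channel_statistics(ch, stats), error = function(e) {
      warn_mf("channel %s: %s; encoded as zeros", ch$name, conditionMessage(e))
      stats_zero <- numeric(length(stats))
      names(stats_zero) <- stats
      stats_zero
    })
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(channels, `[[`, "", "name")
  colnames(m) <- as.character(stats)
  structure(m, modality = mods, stat_set = stats, class = c("ModalFeatureMatrix", "matrix"))
}

#' Write / read a ModalFeatureMatrix as CSV
#'
#' @param m a `ModalFeatureMatrix`.
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(channel_id = rownames(m), modality = attr(m, "modality"),
                   as.data.frame(unclass(m), row.names = NULL),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("channel_id", "modality")), drop = FALSE])
  rownames(m) <- df$channel_id
  structure(m, modality = df$modality[1L], stat_set = stat_set(colnames(m)),
            class = c("ModalFeatureMatrix", "matrix"))
}
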