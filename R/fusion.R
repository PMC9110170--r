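#' Attention configuration
#'
#' Chooses how the query/key similarity is computed before the softmax that
#' yields the modality weights. `cosine` is the default: it is bounded and
#' scale-free, which matters when the three modalities live in different
#' units. `bilinear` uses `k' W q` with an identity `W` unless one is given;
#' `scaled_dot` divides the dot product by `sqrt(d)` with `d` the descriptor
#' length.
#'
#' @param similarity one of `"cosine"`, `"dot"`, `"bilinear"`, `"scaled_dot"`.
#' @param temperature positive softmax temperature (default 1).
#' @param bilinear_matrix square matrix for the bilinear form (default
#'   identity, materialized at call time).
#' @param scale_descriptors z-scale descriptors (fitted on training data)
#'   before the similarity. Off by default: centering the descriptors at
#'   zero makes the cosine between the mean query and each key highly
#'   unstable from sample to sample, which turns the per-sample weights into
#'   multiplicative noise (see the methods vignette).
#' @return An `AttentionConfig`.
#' @export
attention_config <- function(similarity = c("cosine", "dot", "bilinear",
                                            "scaled_dot"),
                             temperature = 1, bilinear_matrix = NULL,
                             scale_descriptors = FALSE) {
  similarity <- match.arg(similarity)
  if (!is_scalar_num(temperature) || temperature <= 0)
    stop_mf("temperature must be positive")
  if (!is.null(bilinear_matrix)) {
    bilinear_matrix <- as.matrix(bilinear_matrix)
    if (nrow(bilinear_matrix) != ncol(bilinear_matrix))
      stop_mf("bilinear_matrix must be square")
  }
  structure(list(similarity = similarity, temperature = temperature,
                 bilinear_matrix = bilinear_matrix,
                 scale_descriptors = isTRUE(scale_descriptors)),
            class = "AttentionConfig")
}

#' Summarize a modality feature matrix into a descriptor vector
#'
#' The attention keys (and the query, via their mean) are per-modality
#' descriptors: the column-wise mean over channels, one value per statistic,
#' optionally z-scaled with parameters fitted on a training set (see
#' [fit_descriptor_scaler()]).
#'
#' @param matrix a `ModalFeatureMatrix` (or plain matrix).
#' @param scaler optional `list(center, scale)` from [fit_descriptor_scaler()].
#' @return Numeric vector of length `ncol(matrix)`.
#' @export
modality_descriptor <- function(matrix, scaler = NULL) {
  m <- unclass(matrix)
  if (!length(m) || !nrow(m)) stop_mf("empty feature matrix")
  d <- colMeans(m)
  if (!is.null(scaler)) d <- (d - scaler$center) / scaler$scale
  d
}

#' Fit a z-scaler for modality descriptors
#'
#' @param descriptors matrix with one training-sample descriptor per row.
#' @return `list(center, scale)`; zero-spread columns get scale 1.
#' @export
fit_descriptor_scaler <- function(descriptors) {
  descriptors <- as.matrix(descriptors)
  ctr <- colMeans(descriptors)
  scl <- apply(descriptors, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' Query/key similarity
#'
#' Implements the four similarity models: dot product `<q,k>`, cosine
#' `<q,k>/(|q||k|)`, bilinear `k' W q`, and scaled dot `<q,k>/sqrt(d)`.
#'
#' @param query,key equal-length numeric vectors.
#' @param config an [attention_config()].
#' @return A scalar similarity.
#' @export
similarity <- function(query, key, config = attention_config()) {
  if (length(query) != length(key))
    stop_mf("query/key length mismatch (%d vs %d)", length(query), length(key))
  switch(config$similarity,
    dot = sum(query * key),
    cosine = {
      nq <- sqrt(sum(query^2)); nk <- sqrt(sum(key^2))
      if (nq == 0 || nk == 0)
        stop_mf("cosine similarity undefined for a zero-norm vector")
      sum(query * key) / (nq * nk)
    },
    bilinear = {
      W <- if (is.null(config$bilinear_matrix)) diag(length(query))
           else config$bilinear_matrix
      if (nrow(W) != length(query)) stop_mf("bilinear_matrix dimension mismatch")
      as.numeric(key %*% W %*% query)
    },
    scaled_dot = sum(query * key) / sqrt(length(query)))
}

#' Softmax attention weights
#'
#' Numerically stable softmax (max-subtraction) of the similarity scores
#' divided by the temperature.
#'
#' @param similarities numeric vector of similarity scores (finite).
#' @param temperature positive scalar.
#' @return Weights of the same length, positive, summing to 1.
#' @export
attention_weights <- function(similarities, temperature = 1) {
  if (any(!is.finite(similarities))) stop_mf("similarities must be finite")
  if (!is_scalar_num(temperature) || temperature <= 0)
    stop_mf("temperature must be positive")
  z <- similarities / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

#' Attention-weighted feature fusion
#'
#' Computes one descriptor per modality (keys), takes their element-wise mean
#' as the query, scores each key against the query, softmax-normalizes the
#' scores into weights `(w_face, w_voice, w_gait)`, scales each modality
#' feature matrix by its weight and stacks the blocks in the fixed row order
#' face, gait, voice. With the default 68x4 / 17x4 / 18x4 inputs the fused
#' matrix is 103 x 4 and flattens row-major to a 412-vector.
#'
#' @param Ffea,Vfea,Gfea face / voice / gait `ModalFeatureMatrix` objects
#'   sharing a statistic set.
#' @param config an [attention_config()].
#' @param scalers optional named list (`face`, `voice`, `gait`) of descriptor
#'   scalers fitted on training data.
#' @param weight_override optional numeric length-3 override
#'   `(face, voice, gait)`; bypasses similarity/softmax entirely (values need
#'   not sum to 1, e.g. `c(1,1,1)` reproduces plain concatenation).
#' @return A `FusedFeature`: list with `matrix` (rows face, gait, voice),
#'   `weights` (named, face/voice/gait), `similarities`, `block_index`.
#' @export
fuse <- function(Ffea, Vfea, Gfea, config = attention_config(),
                 scalers = NULL, weight_override = NULL) {
  mats <- list(face = unclass(Ffea), voice = unclass(Vfea), gait = unclass(Gfea))
  ncols <- vapply(mats, ncol, 0L)
  if (length(unique(ncols)) != 1L)
    stop_mf("modality matrices must share the statistic columns (got %s)",
            paste(ncols, collapse = ", "))
  if (is.null(weight_override)) {
    keys <- lapply(names(mats), function(m)
      modality_descriptor(mats[[m]], scalers[[m]]))
    names(keys) <- names(mats)
    query <- Reduce(`+`, keys) / length(keys)
    sims <- vapply(keys, function(k) similarity(query, k, config), numeric(1))
    w <- attention_weights(sims, config$temperature)
  } else {
    if (length(weight_override) != 3L)
      stop_mf("weight_override must have length 3 (face, voice, gait)")
    w <- as.numeric(weight_override)
    names(w) <- names(mats)
    sims <- rep(NA_real_, 3L)
    names(sims) <- names(mats)
  }
  blocks <- list(face = w[["face"]] * mats$face,
                 gait = w[["gait"]] * mats$gait,
                 voice = w[["voice"]] * mats$voice)
  fused <- do.call(rbind, blocks)
  block_index <- rep(c("face", "gait", "voice"),
                     times = c(nrow(mats$face), nrow(mats$gait), nrow(mats$voice)))
  structure(list(matrix = fused, weights = w, similarities = sims,
                 block_index = block_index),
            class = "FusedFeature")
}

#' Flatten a fused feature row-major for classification
#'
#' @param fused a [fuse()] result.
#' @return Numeric vector of length `nrow * ncol` (412 under defaults).
#' @export
flatten_fused <- function(fused) {
  stopifnot(inherits(fused, "FusedFeature"))
  as.numeric(t(fused$matrix))
}

#' Cohort-level (global) attention weights
#'
#' The per-sample weights averaged over a set of subjects — the "global"
#' alternative to per-sample weighting when a single modality ranking per
#' dataset is wanted.
#'
#' @param dataset a `CohortFeatures` object.
#' @param config an [attention_config()].
#' @return Named numeric vector (face, voice, gait) summing to 1.
#' @export
average_attention_weights <- function(dataset, config = attention_config()) {
  stopifnot(inherits(dataset, "CohortFeatures"))
  w <- vapply(dataset$subjects, function(s)
    fuse(s$face, s$voice, s$gait, config)$weights, numeric(3))
  out <- rowMeans(w)
  out / sum(out)
}

#' @export
print.FusedFeature <- function(x, ...) {
  cat(sprintf("FusedFeature: %d x %d (face %d, gait %d, voice %d rows)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$block_index == "face"), sum(x$block_index == "gait"),
              sum(x$block_index == "voice")))
  cat(sprintf("weights: face %.4f, voice %.4f, gait %.4f\n",
              x$weights[["face"]], x$weights[["voice"]], x$weights[["gait"]]))
  invisible(x)
}
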