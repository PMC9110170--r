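#' The ten mental-health indicators
#'
#' Names of the ten binary indicators scored by the classifier bank
#' (an SCL-90-style symptom checklist); positive means the subject screens
#' positive for that indicator.
#'
#' @return Character vector of length 10.
#' @export
indicator_names <- function() {
  c("somatization", "obsessive_compulsive", "interpersonal_sensitivity",
    "depression", "anxiety", "hostility", "dreadness", "crankiness",
    "psychopathy", "other")
}

#' Gaussian (RBF) kernel
#'
#' `K(x, z) = exp(-||x - z||^2 / (2 sigma^2))`.
#'
#' @param x,z equal-length numeric vectors.
#' @param sigma positive kernel width.
#' @return Kernel value in `(0, 1]`.
#' @export
gaussian_kernel <- function(x, z, sigma) {
  if (length(x) != length(z)) stop_mf("x/z length mismatch")
  if (!is_scalar_num(sigma) || sigma <= 0) stop_mf("sigma must be positive")
  exp(-sum((x - z)^2) / (2 * sigma^2))
}

# Gaussian kernel matrix between row sets A (n x d) and B (m x d).
kernel_matrix <- function(A, B, sigma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

# Fit one soft-margin Gaussian SVM on pre-standardized features. With
# class_weight, each sample's penalty is scaled by n/(2 * n_class) so the
# minority class is penalized more heavily for margin violations.
svm_fit <- function(X, y01, C, sigma, tol = 1e-3, max_passes = 60L,
                    class_weight = FALSE) {
  y <- ifelse(y01 > 0, 1, -1)
  Cvec <- rep(C, length(y))
  if (isTRUE(class_weight)) {
    n <- length(y)
    Cvec <- C * n / (2 * ifelse(y > 0, sum(y > 0), sum(y < 0)))
  }
  K <- kernel_matrix(X, X, sigma)
  sol <- cpp_smo(K, y, Cvec, tol, as.integer(max_passes))
  sv <- which(sol$alpha > 1e-8)
  list(sv_x = X[sv, , drop = FALSE], sv_coef = sol$alpha[sv] * y[sv],
       b = sol$b, sigma = sigma)
}

svm_decision <- function(model, X) {
  as.numeric(kernel_matrix(X, model$sv_x, model$sigma) %*% model$sv_coef +
               model$b)
}

#' Train the ten-indicator SVM bank
#'
#' Binary relevance: one independent soft-margin Gaussian-kernel SVM per
#' indicator, trained on standardized features (standardization parameters
#' are fitted here and stored). The default penalty is `C = 1`; the default
#' kernel width follows the "scale" rule `sigma^2 = d * Var(X) / 2` with
#' `Var(X)` the mean per-dimension variance of the standardized features
#' (equivalently, kernel coefficient `1/(d * Var)`). A `degree` argument is
#' accepted for configuration fidelity but ignored: it parameterizes a
#' polynomial kernel, not the Gaussian one.
#'
#' @param features numeric matrix, one flattened fused feature per row.
#' @param labels numeric/integer matrix `n x 10` of 0/1 indicator states
#'   (columns in [indicator_names()] order).
#' @param C soft-margin penalty (default 1).
#' @param sigma_rule `"scale"` (default) or `"fixed"` (then give `sigma`).
#' @param sigma kernel width when `sigma_rule = "fixed"`.
#' @param degree accepted and ignored (polynomial-kernel parameter).
#' @param class_weight inverse-frequency class weighting (default off): each
#'   sample's penalty becomes `C * n / (2 * n_class)`.
#' @return A `ClassifierBank`.
#' @export
train_bank <- function(features, labels, C = 1, sigma_rule = c("scale", "fixed"),
                       sigma = NULL, degree = 3, class_weight = FALSE) {
  sigma_rule <- match.arg(sigma_rule)
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (nrow(features) != nrow(labels))
    stop_mf("features/labels row mismatch (%d vs %d)",
            nrow(features), nrow(labels))
  if (ncol(labels) != 10L) stop_mf("labels must have 10 indicator columns")
  if (is.null(colnames(labels))) colnames(labels) <- indicator_names()
  for (ind in colnames(labels)) {
    counts <- table(factor(labels[, ind], levels = c(0, 1)))
    if (any(counts < 2L))
      stop_mf("indicator '%s' needs at least 2 samples of each class (got %d/%d)",
              ind, counts[[1L]], counts[[2L]])
  }
  ctr <- colMeans(features)
  scl <- apply(features, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  X <- sweep(sweep(features, 2L, ctr), 2L, scl, `/`)
  if (sigma_rule == "scale") {
    v <- mean(apply(X, 2L, var))
    if (v <= 0) v <- 1
    sigma <- sqrt(ncol(X) * v / 2)
  } else if (is.null(sigma) || sigma <= 0) {
    stop_mf("sigma_rule = 'fixed' requires a positive sigma")
  }
  models <- lapply(colnames(labels), function(ind)
    svm_fit(X, labels[, ind], C = C, sigma = sigma,
            class_weight = class_weight))
  names(models) <- colnames(labels)
  structure(list(models = models, center = ctr, scale = scl, sigma = sigma,
                 C = C, indicators = colnames(labels)),
            class = "ClassifierBank")
}

#' Predict indicator states
#'
#' @param object a `ClassifierBank`.
#' @param features numeric vector (one sample) or matrix (one row per sample)
#'   matching the training dimension.
#' @param type `"class"` for 0/1 labels, `"score"` for decision values.
#' @param ... unused.
#' @return Matrix `n x 10` of labels or scores.
#' @export
predict.ClassifierBank <- function(object, features, type = c("class", "score"),
                                   ...) {
  type <- match.arg(type)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != length(object$center))
    stop_mf("feature length %d does not match training dimension %d",
            ncol(features), length(object$center))
  X <- sweep(sweep(features, 2L, object$center), 2L, object$scale, `/`)
  scores <- vapply(object$indicators,
                   function(ind) svm_decision(object$models[[ind]], X),
                   numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X),
                   dimnames = list(NULL, object$indicators))
  if (type == "score") scores else (scores >= 0) + 0L
}

#' Save / load a classifier bank
#'
#' JSON persistence of all per-indicator parameters and the feature scaler.
#'
#' @param bank a `ClassifierBank`.
#' @param path file path.
#' @return `path` / the bank.
#' @export
save_bank <- function(bank, path) {
  stopifnot(inherits(bank, "ClassifierBank"))
  payload <- list(
    sigma = bank$sigma, C = bank$C, indicators = bank$indicators,
    center = bank$center, scale = bank$scale,
    models = lapply(bank$models, function(m)
      list(sv_x = m$sv_x, sv_coef = m$sv_coef, b = m$b, sigma = m$sigma)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  models <- lapply(p$models, function(m)
    list(sv_x = as.matrix(m$sv_x), sv_coef = as.numeric(m$sv_coef),
         b = m$b, sigma = m$sigma))
  structure(list(models = models, center = as.numeric(p$center),
                 scale = as.numeric(p$scale), sigma = p$sigma, C = p$C,
                 indicators = p$indicators),
            class = "ClassifierBank")
}
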