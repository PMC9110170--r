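#' Confusion counts
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return A `ConfusionCounts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) stop_mf("truth/pred length mismatch")
  structure(list(TP = sum(truth == 1 & pred == 1),
                 TN = sum(truth == 0 & pred == 0),
                 FP = sum(truth == 0 & pred == 1),
                 FN = sum(truth == 1 & pred == 0)),
            class = "ConfusionCounts")
}

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `recall = TP/(TP+FN)`,
#' `precision = TP/(TP+FP)`, `F1 = 2*precision*recall/(precision+recall)`.
#' Zero-denominator conventions: precision and recall are 0 when their
#' denominator is 0, and F1 is 0 when `precision + recall = 0`.
#'
#' @param counts a [confusion_counts()] (or list with TP/TN/FP/FN).
#' @return Named numeric vector `(accuracy, precision, recall, F1)`.
#' @export
metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, tn, fp, fn) < 0)) stop_mf("counts must be non-negative")
  total <- tp + tn + fp + fn
  if (total == 0) stop_mf("no evaluated samples (all counts zero)")
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / total, precision = precision, recall = recall,
    F1 = f1)
}

# ---- condition feature builders ------------------------------------------

modality_block_order <- c("face", "gait", "voice")

# Plain concatenation of the selected modality blocks (row-major flatten),
# one row per subject. Used by the no-attention conditions.
concat_features <- function(dataset, modalities) {
  t(vapply(dataset$subjects, function(s) {
    unlist(lapply(intersect(modality_block_order, modalities),
                  function(m) as.numeric(t(unclass(s[[m]])))))
  }, numeric(feature_dim(dataset, modalities))))
}

feature_dim <- function(dataset, modalities) {
  s <- dataset$subjects[[1L]]
  sum(vapply(modalities, function(m) length(unclass(s[[m]])), 0L))
}

# Attention-weighted features for the selected modalities; weights are
# computed per sample (softmax over however many modalities are selected).
# When config$scale_descriptors is on, descriptor z-scalers are fitted on
# the training subjects only.
attention_features <- function(dataset, modalities, train_idx, config) {
  mods <- intersect(modality_block_order, modalities)
  scalers <- if (config$scale_descriptors) {
    sc <- lapply(mods, function(m) {
      descs <- t(vapply(dataset$subjects[train_idx],
                        function(s) modality_descriptor(s[[m]]),
                        numeric(ncol(unclass(dataset$subjects[[1L]][[m]])))))
      fit_descriptor_scaler(descs)
    })
    names(sc) <- mods
    sc
  } else NULL
  t(vapply(dataset$subjects, function(s) {
    keys <- lapply(mods, function(m) modality_descriptor(s[[m]], scalers[[m]]))
    query <- Reduce(`+`, keys) / length(keys)
    sims <- vapply(keys, function(k) similarity(query, k, config), numeric(1))
    w <- attention_weights(sims, config$temperature)
    unlist(lapply(seq_along(mods),
                  function(i) as.numeric(t(w[i] * unclass(s[[mods[i]]])))))
  }, numeric(feature_dim(dataset, mods))))
}

# ---- cross-validation -----------------------------------------------------

# Stratified fold assignment for one 0/1 label vector. A single counter runs
# across both (shuffled) classes so folds stay balanced for any k, and k = n
# degenerates cleanly to leave-one-out (every sample its own fold).
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  ctr <- 0L
  for (cls in c(0, 1)) {
    for (i in sample(which(y == cls))) {
      folds[i] <- ctr %% k + 1L
      ctr <- ctr + 1L
    }
  }
  folds
}

fit_predict_one <- function(Xtr, ytr, Xte, C, sigma_rule, sigma = NULL) {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Str <- sweep(sweep(Xtr, 2L, ctr), 2L, scl, `/`)
  Ste <- sweep(sweep(Xte, 2L, ctr), 2L, scl, `/`)
  if (sigma_rule == "scale") {
    v <- mean(apply(Str, 2L, var))
    if (v <= 0) v <- 1
    sigma <- sqrt(ncol(Str) * v / 2)
  }
  model <- svm_fit(Str, ytr, C = C, sigma = sigma)
  (svm_decision(model, Ste) >= 0) + 0L
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each indicator independently (binary relevance): assign stratified
#' folds, and for each fold build the condition features (attention scalers
#' fitted on the training subjects only), train a Gaussian-kernel SVM on the
#' training part and predict the held-out part. Out-of-fold predictions are
#' pooled per indicator and summarized with [metrics()]; the overall numbers
#' are macro-averages over the ten indicators.
#'
#' @param dataset a `CohortFeatures` object (see [extract_cohort_features()]).
#' @param k number of folds (default 5; `k = n` gives leave-one-out).
#' @param seed fold-assignment seed (default 42).
#' @param modalities subset of `c("face", "voice", "gait")`.
#' @param attention use attention weighting (default TRUE; needs >= 2
#'   modalities, otherwise features are plain concatenation).
#' @param config an [attention_config()].
#' @param C,sigma_rule,sigma SVM hyperparameters as in [train_bank()].
#' @param condition label recorded in the report.
#' @return An `EvalReport`.
#' @export
cross_validate <- function(dataset, k = 5L, seed = 42L,
                           modalities = c("face", "voice", "gait"),
                           attention = TRUE, config = attention_config(),
                           C = 1, sigma_rule = "scale", sigma = NULL,
                           condition = NULL) {
  stopifnot(inherits(dataset, "CohortFeatures"))
  n <- length(dataset$subjects)
  if (k < 2L || k > n) stop_mf("k must be in [2, n]")
  mods <- intersect(modality_block_order, modalities)
  if (!length(mods)) stop_mf("no modalities selected")
  missing <- setdiff(mods, names(dataset$subjects[[1L]]))
  if (length(missing))
    stop_mf("dataset lacks modality: %s", paste(missing, collapse = ", "))
  use_att <- attention && length(mods) >= 2L
  labels <- dataset$labels
  if (is.null(condition))
    condition <- paste0(paste(toupper(substr(mods, 1, 1)), collapse = "+"),
                        if (use_att) "+attention" else "")
  plain_X <- if (!use_att) concat_features(dataset, mods)
  fold_matrix <- matrix(NA_integer_, n, ncol(labels),
                        dimnames = list(NULL, colnames(labels)))
  per_ind <- lapply(colnames(labels), function(ind) {
    y <- labels[, ind]
    if (length(unique(y)) < 2L)
      stop_mf("indicator '%s' has a single class; cannot cross-validate", ind)
    folds <- with_seed(child_seed(seed, match(ind, colnames(labels))),
                       stratified_folds(y, k))
    fold_matrix[, ind] <<- folds
    pred <- integer(n)
    for (f in seq_len(k)) {
      te <- which(folds == f); tr <- which(folds != f)
      if (length(unique(y[tr])) < 2L)
        stop_mf("training part of fold %d is single-class for '%s'; use fewer folds or more data",
                f, ind)
      X <- if (use_att) attention_features(dataset, mods, tr, config)
           else plain_X
      pred[te] <- fit_predict_one(X[tr, , drop = FALSE], y[tr],
                                  X[te, , drop = FALSE], C, sigma_rule, sigma)
    }
    metrics(confusion_counts(y, pred))
  })
  tab <- data.frame(indicator = colnames(labels),
                    do.call(rbind, per_ind), row.names = NULL)
  structure(list(condition = condition, table = tab,
                 overall_accuracy = mean(tab$accuracy),
                 overall_F1 = mean(tab$F1),
                 folds = fold_matrix, k = k, seed = seed),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, digits = 4, ...) {
  cat(sprintf("EvalReport [%s]: overall accuracy %.4f, overall F1 %.4f (k=%d, seed=%d)\n",
              x$condition, x$overall_accuracy, x$overall_F1, x$k, x$seed))
  print(cbind(indicator = x$table$indicator,
              round(x$table[, -1L], digits)), row.names = FALSE)
  invisible(x)
}

#' Modality-ablation experiment grid
#'
#' Evaluates the eight conditions: each single modality (F, V, G), each pair
#' (plain concatenation), the tri-modal plain concatenation, and the
#' tri-modal attention-weighted fusion. Conditions requiring an absent
#' modality are skipped with a warning.
#'
#' @param dataset a `CohortFeatures` object.
#' @param seed fold seed shared by every condition.
#' @param k folds.
#' @param config attention configuration for the attention condition.
#' @param C SVM penalty.
#' @return Named list of `EvalReport`s.
#' @export
ablation_grid <- function(dataset, seed = 42L, k = 5L,
                          config = attention_config(), C = 1) {
  grid <- list(
    "F" = list(mods = "face", att = FALSE),
    "V" = list(mods = "voice", att = FALSE),
    "G" = list(mods = "gait", att = FALSE),
    "F+V" = list(mods = c("face", "voice"), att = FALSE),
    "F+G" = list(mods = c("face", "gait"), att = FALSE),
    "V+G" = list(mods = c("voice", "gait"), att = FALSE),
    "F+V+G" = list(mods = c("face", "voice", "gait"), att = FALSE),
    "F+V+G+attention" = list(mods = c("face", "voice", "gait"), att = TRUE))
  present <- names(dataset$subjects[[1L]])
  out <- list()
  for (nm in names(grid)) {
    g <- grid[[nm]]
    if (!all(g$mods %in% present)) {
      warn_mf("condition %s skipped: modality missing from dataset", nm)
      next
    }
    out[[nm]] <- cross_validate(dataset, k = k, seed = seed,
                                modalities = g$mods, attention = g$att,
                                config = config, C = C, condition = nm)
  }
  out
}

#' Flatten an ablation result into one table
#'
#' @param reports result of [ablation_grid()].
#' @return data.frame with condition x indicator x metric rows plus overall
#'   rows.
#' @export
ablation_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    rbind(data.frame(condition = r$condition, r$table),
          data.frame(condition = r$condition, indicator = "overall",
                     accuracy = r$overall_accuracy, precision = NA,
                     recall = NA, F1 = r$overall_F1))
  }))
}
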