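# Repeated stratified k-fold cross-validation and confusion-matrix metrics.

#' Confusion-matrix metrics for a binary prediction
#'
#' Accuracy, sensitivity and specificity with class 1 as positive. When the
#' truth contains a single class the undefined rate is `NA`.
#'
#' @param pred_class Predicted 0/1 classes.
#' @param truth Observed 0/1 classes.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
binary_metrics <- function(pred_class, truth) {
  stopifnot(length(pred_class) == length(truth))
  acc <- mean(pred_class == truth)
  sens <- if (any(truth == 1)) mean(pred_class[truth == 1] == 1) else NA_real_
  spec <- if (any(truth == 0)) mean(pred_class[truth == 0] == 0) else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

# stratified fold assignment: within each class, samples are dealt to folds
# in random order; fold sizes differ by at most one per class
stratified_folds <- function(y, k, stratify) {
  n <- length(y)
  fold <- integer(n)
  groups <- if (stratify) split(seq_len(n), y) else list(seq_len(n))
  offset <- 0L
  for (idx in groups) {
    perm <- idx[sample.int(length(idx))]
    fold[perm] <- ((seq_along(perm) + offset - 1L) %% k) + 1L
    offset <- offset + length(idx) # stagger so overall fold sizes balance
  }
  fold
}

#' Repeated stratified k-fold cross-validation of a random GLM ensemble
#'
#' For each repeat the data are partitioned into `k` folds (stratified by
#' class for a binary outcome); each fold is predicted by an ensemble
#' trained on the remaining folds, and the assembled predictions of the
#' whole partition are scored. Binary outcomes report accuracy,
#' sensitivity and specificity; continuous ones the Pearson correlation
#' between predictions and truth.
#'
#' @param x,y Data to cross-validate.
#' @param k Number of folds (default 3).
#' @param n_repeats Number of random partitions (default 100).
#' @param seed Master seed governing partitions and model fits.
#' @param ... Passed to [rglm()] (e.g. `n_bags`, `max_interaction_order`).
#' @return Object of class `rglm_cv`: `per_repeat` data frame (one row per
#'   partition), `mean_accuracy`, `median_accuracy`, and for binary
#'   outcomes mean sensitivity/specificity.
#' @export
rglm_cv <- function(x, y, k = 3L, n_repeats = 100L, seed = 1L, ...) {
  stopifnot(k >= 2)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  binary <- all(y %in% c(0, 1))
  seeds <- derive_seeds(seed, 2L * n_repeats)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- with_seed(seeds[2L * r - 1L], stratified_folds(y, k, binary))
    pred <- rep(NA_real_, n)
    cls <- rep(NA_integer_, n)
    skipped <- FALSE
    for (f in seq_len(k)) {
      test <- fold == f
      y_tr <- y[!test]
      if (binary && length(unique(y_tr)) < 2L) {
        warning("fold with single-class training outcome: repeat skipped")
        skipped <- TRUE
        break
      }
      fit <- rglm(x[!test, , drop = FALSE], y_tr,
                  seed = seeds[2L * r], ...)
      pred[test] <- predict(fit, x[test, , drop = FALSE])
      if (binary) {
        cls[test] <- as.integer(pred[test] >= fit$config$classify_threshold)
      }
    }
    if (skipped) next
    rows[[r]] <- if (binary) {
      as.list(binary_metrics(cls, y))
    } else {
      list(accuracy = suppressWarnings(cor(pred, y)))
    }
  }
  per_repeat <- do.call(rbind, lapply(Filter(Negate(is.null), rows),
                                      as.data.frame))
  out <- list(per_repeat = per_repeat,
              mean_accuracy = mean(per_repeat$accuracy),
              median_accuracy = median(per_repeat$accuracy),
              k = k, n_repeats = n_repeats, binary = binary)
  if (binary) {
    out$mean_sensitivity <- mean(per_repeat$sensitivity, na.rm = TRUE)
    out$mean_specificity <- mean(per_repeat$specificity, na.rm = TRUE)
  }
  structure(out, class = "rglm_cv")
}

#' @export
print.rglm_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d partitions: mean accuracy %.3f, median %.3f\n",
              x$k, nrow(x$per_repeat), x$mean_accuracy, x$median_accuracy))
  if (isTRUE(x$binary)) {
    cat(sprintf("  mean sensitivity %.3f, mean specificity %.3f\n",
                x$mean_sensitivity, x$mean_specificity))
  }
  invisible(x)
}
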