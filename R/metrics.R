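#' Area under the ROC curve
#'
#' Rank-based AUC (equivalent to the normalized Mann-Whitney U statistic),
#' with tied scores handled by midranks. A constant score therefore gives
#' exactly 0.5.
#'
#' @param scores Numeric prediction scores, higher meaning more lncRNA-like.
#' @param truth True labels (`"lncRNA"`/`"coding"`, factor, or 0/1 with 1 =
#'   lncRNA).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, truth) {
  y <- as_label_factor(truth)
  pos <- y == "lncRNA"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("AUC needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion counts from predicted and true labels
#'
#' @param pred,truth Label vectors (`"lncRNA"`/`"coding"` or 0/1); lncRNA is
#'   the positive class.
#' @return Named integer vector `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_counts <- function(pred, truth) {
  p <- as_label_factor(pred) == "lncRNA"
  t <- as_label_factor(truth) == "lncRNA"
  c(TP = sum(p & t), FN = sum(!p & t), TN = sum(!p & !t), FP = sum(p & !t))
}

#' Classification metrics report
#'
#' Accuracy, sensitivity (lncRNA recall), specificity, precision and F1 from
#' confusion counts, plus AUC when scores are supplied. Metrics with a zero
#' denominator are reported as `NA` (undefined), not coerced to 0.
#'
#' @param counts Named vector with `TP`, `FN`, `TN`, `FP` (see
#'   [confusion_counts()]).
#' @param scores Optional numeric scores for AUC.
#' @param truth Optional true labels matching `scores`.
#' @return A one-row tibble with columns `AUC`, `ACC`, `SN`, `SP`, `PRE`,
#'   `F1`.
#' @examples
#' compute_metrics(c(TP = 8, FN = 2, TN = 9, FP = 1))
#' @export
compute_metrics <- function(counts, scores = NULL, truth = NULL) {
  stopifnot(all(c("TP", "FN", "TN", "FP") %in% names(counts)),
            all(counts >= 0))
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]; fp <- counts[["FP"]]
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  f1 <- if (!is.na(pre) && !is.na(sn) && (pre + sn) > 0) {
    2 * pre * sn / (pre + sn)
  } else {
    NA_real_
  }
  auc <- if (!is.null(scores)) auc_score(scores, truth) else NA_real_
  tibble::tibble(AUC = auc, ACC = acc, SN = sn, SP = sp, PRE = pre, F1 = f1)
}

#' Seeded stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that both classes are spread as
#' evenly as possible across folds; the assignment is deterministic for a
#' given seed.
#'
#' @param truth Label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(truth, k = 10, seed = 1) {
  y <- as_label_factor(truth)
  stopifnot(k >= 2)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < k && length(idx) > 0) {
        rlang::warn(sprintf("class '%s' has fewer samples than folds", cl))
      }
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validate a model-fitting routine
#'
#' Seeded stratified k-fold cross-validation: the data are split into `k`
#' equally sized folds, each fold serves once as the test set while the model
#' is fitted on the rest, and metrics are reported per fold, as the fold mean,
#' and pooled over all held-out scores.
#'
#' @param X Feature matrix or feature tibble.
#' @param y True labels.
#' @param fit_fun `function(X_train, y_train)` returning a fitted model.
#' @param predict_fun `function(model, X_test)` returning lncRNA scores in
#'   \[0, 1\].
#' @param folds Number of folds.
#' @param seed Integer seed controlling the fold split.
#' @param threshold Score threshold for the label-based metrics.
#' @return An object of class `lnc_cv`: list with `per_fold` (tibble),
#'   `mean` (one-row tibble), `pooled` (one-row tibble), `scores`, `truth`,
#'   `fold_ids`.
#' @export
cross_validate <- function(X, y, fit_fun, predict_fun, folds = 10, seed = 1,
                           threshold = 0.5) {
  if (is.data.frame(X)) X <- feature_matrix(X, schema_names = NULL)
  y <- as_label_factor(y)
  fold_ids <- stratified_folds(y, k = folds, seed = seed)
  scores <- numeric(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_ids == f
    model <- fit_fun(X[!test, , drop = FALSE], y[!test])
    s <- predict_fun(model, X[test, , drop = FALSE])
    scores[test] <- s
    pred <- ifelse(s >= threshold, "lncRNA", "coding")
    per_fold[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f),
      compute_metrics(confusion_counts(pred, y[test]), scores = s,
                      truth = y[test])
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  pooled_pred <- ifelse(scores >= threshold, "lncRNA", "coding")
  pooled <- compute_metrics(confusion_counts(pooled_pred, y),
                            scores = scores, truth = y)
  mean_row <- dplyr::summarise(
    per_fold, dplyr::across(c("AUC", "ACC", "SN", "SP", "PRE", "F1"),
                            ~ mean(.x, na.rm = TRUE))
  )
  structure(
    list(per_fold = per_fold, mean = mean_row, pooled = pooled,
         scores = scores, truth = y, fold_ids = fold_ids),
    class = "lnc_cv"
  )
}

#' @export
print.lnc_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (n = %d)\n",
              max(x$fold_ids), length(x$truth)))
  cat("Fold-mean metrics:\n")
  print(x$mean)
  invisible(x)
}

#' ROC curve plot for cross-validation results
#'
#' @param object An `lnc_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lnc_cv
#' @export
autoplot.lnc_cv <- function(object, ...) {
  y <- object$truth == "lncRNA"
  ord <- order(object$scores, decreasing = TRUE)
  tpr <- cumsum(y[ord]) / sum(y)
  fpr <- cumsum(!y[ord]) / sum(!y)
  df <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Pooled ROC (AUC = %.3f)", object$pooled$AUC)
    ) +
    ggplot2::theme_minimal()
}
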