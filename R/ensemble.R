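#' Train the stacked random-forest ensemble
#'
#' The two-layer stacked model: one random forest is trained per optimal
#' feature subset (10 subsets in the standard configuration), and the output
#' layer averages the positive-class (lncRNA) probabilities of all members.
#'
#' @param X Feature tibble or matrix aligned to the 260-feature schema (or any
#'   fixed column set; the column names are hashed and verified at prediction
#'   time).
#' @param y Labels (lncRNA positive).
#' @param subsets A list of 0/1 gene vectors (one per member) or an `lnc_ga`
#'   object, whose `subsets` are used.
#' @param rf_trees Trees per member forest.
#' @param seed Integer seed; member `i` trains with seed `seed + i`.
#' @param threshold Score threshold used by [predict_label()].
#' @param hexamer_table Optional `lnc_hexamer_table` embedded in the model so
#'   that prediction can start from raw FASTA.
#' @return An object of class `lnc_stack`.
#' @export
train_stacked <- function(X, y, subsets, rf_trees = 100, seed = 1,
                          threshold = 0.5, hexamer_table = NULL) {
  if (inherits(subsets, "lnc_ga")) subsets <- subsets$subsets
  stopifnot(is.list(subsets), length(subsets) >= 1)
  if (is.data.frame(X)) X <- feature_matrix(X, schema_names = NULL)
  y <- as_label_factor(y)
  feature_names <- colnames(X)
  members <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    genes <- as.integer(subsets[[i]])
    stopifnot(length(genes) == ncol(X))
    cols <- which(genes == 1L)
    if (length(cols) == 0) rlang::abort("member mask selects no features")
    fit <- ranger::ranger(x = X[, cols, drop = FALSE], y = y,
                          num.trees = rf_trees, probability = TRUE,
                          num.threads = 1, seed = seed + i, verbose = FALSE)
    members[[i]] <- list(mask = genes, fit = fit, seed = seed + i)
  }
  structure(
    list(members = members, n_members = length(members),
         feature_names = feature_names,
         schema_hash = rlang::hash(feature_names),
         rf_trees = rf_trees, seed = seed, threshold = threshold,
         hexamer_table = hexamer_table,
         positive_class = "lncRNA"),
    class = "lnc_stack"
  )
}

check_schema <- function(model, X) {
  if (is.data.frame(X)) X <- feature_matrix(X, schema_names = NULL)
  if (!identical(rlang::hash(colnames(X)), model$schema_hash)) {
    rlang::abort("feature columns do not match the schema this model was trained on")
  }
  X
}

#' Ensemble lncRNA score
#'
#' Arithmetic mean of the member forests' lncRNA probabilities.
#'
#' @param model An `lnc_stack` model.
#' @param X Feature tibble or matrix with the columns the model was trained
#'   on.
#' @return Numeric scores in \[0, 1\], one per row of `X`.
#' @export
predict_score <- function(model, X) {
  stopifnot(inherits(model, "lnc_stack"))
  X <- check_schema(model, X)
  scores <- matrix(0, nrow = nrow(X), ncol = model$n_members)
  for (i in seq_along(model$members)) {
    m <- model$members[[i]]
    cols <- which(m$mask == 1L)
    scores[, i] <- stats::predict(
      m$fit, data = X[, cols, drop = FALSE],
      num.threads = 1)$predictions[, "lncRNA"]
  }
  rowMeans(scores)
}

#' Ensemble label prediction
#'
#' Labels a transcript lncRNA when its averaged score is greater than or equal
#' to the model threshold (ties resolve toward lncRNA).
#'
#' @inheritParams predict_score
#' @param threshold Optional override of the model threshold.
#' @return Factor with levels `coding`, `lncRNA`.
#' @export
predict_label <- function(model, X, threshold = model$threshold) {
  s <- predict_score(model, X)
  factor(ifelse(s >= threshold, "lncRNA", "coding"),
         levels = c("coding", "lncRNA"))
}

#' @export
predict.lnc_stack <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  if (type == "score") predict_score(object, newdata)
  else predict_label(object, newdata)
}

#' Save / load a stacked model
#'
#' The archive embeds the member forests, their feature masks, the schema
#' hash, the seeds, the threshold and (when present) the hexamer table, so a
#' loaded model reproduces predictions exactly. Loading verifies the stored
#' feature names against their hash and fails on mismatch.
#'
#' @param model An `lnc_stack` model.
#' @param path File path.
#' @return `path` (save) or an `lnc_stack` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lnc_stack"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "lnc_stack")) {
    rlang::abort("file does not contain a stacked model")
  }
  if (!identical(rlang::hash(model$feature_names), model$schema_hash)) {
    rlang::abort("model schema hash mismatch: file corrupt or schema changed")
  }
  model
}

#' @export
print.lnc_stack <- function(x, ...) {
  cat(sprintf(
    "Stacked ensemble: %d random forests (%d trees each), threshold %.2f\n",
    x$n_members, x$rf_trees, x$threshold))
  cat(sprintf("Features per member: %s\n",
              paste(vapply(x$members, function(m) sum(m$mask), numeric(1)),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy a stacked model
#'
#' @param x An `lnc_stack` model.
#' @param ... Unused.
#' @return A tibble with one row per member: `member`, `n_features`, `seed`,
#'   `oob_error` (ranger's out-of-bag prediction error).
#' @method tidy lnc_stack
#' @export
tidy.lnc_stack <- function(x, ...) {
  tibble::tibble(
    member = seq_along(x$members),
    n_features = vapply(x$members, function(m) sum(m$mask), numeric(1)),
    seed = vapply(x$members, function(m) m$seed, numeric(1)),
    oob_error = vapply(x$members, function(m) m$fit$prediction.error,
                       numeric(1))
  )
}

#' One-row summary of a stacked model
#'
#' @param x An `lnc_stack` model.
#' @param ... Unused.
#' @return A one-row tibble: `n_members`, `rf_trees`, `threshold`,
#'   `mean_n_features`.
#' @method glance lnc_stack
#' @export
glance.lnc_stack <- function(x, ...) {
  tibble::tibble(
    n_members = x$n_members,
    rf_trees = x$rf_trees,
    threshold = x$threshold,
    mean_n_features = mean(vapply(x$members, function(m) sum(m$mask),
                                  numeric(1)))
  )
}

#' Score-distribution plot for a prediction set
#'
#' @param scores Numeric lncRNA scores.
#' @param truth Optional true labels for colouring.
#' @param threshold Decision threshold to mark.
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, truth = NULL, threshold = 0.5) {
  df <- tibble::tibble(score = scores)
  if (!is.null(truth)) {
    df$truth <- as_label_factor(truth)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$truth))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score))
  }
  p +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Ensemble lncRNA score", y = "Transcripts") +
    ggplot2::theme_minimal()
}
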