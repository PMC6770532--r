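test_that("confusion-count metrics match direct substitution", {
  perfect <- compute_metrics(c(TP = 1, FN = 0, TN = 1, FP = 0))
  expect_equal(unlist(perfect[, c("ACC", "SN", "SP", "PRE", "F1")]),
               c(ACC = 1, SN = 1, SP = 1, PRE = 1, F1 = 1))

  m <- compute_metrics(c(TP = 8, FN = 2, TN = 9, FP = 1))
  expect_equal(m$ACC, 0.85)
  expect_equal(m$SN, 0.8)
  expect_equal(m$SP, 0.9)
  expect_equal(m$PRE, 8 / 9)
  expect_equal(m$F1, 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8))
  expect_equal(round(m$F1, 4), 0.8421)

  undef <- compute_metrics(c(TP = 0, FN = 5, TN = 5, FP = 0))
  expect_true(is.na(undef$PRE))
  expect_true(is.na(undef$F1))
  expect_equal(undef$SP, 1)
})

test_that("F1 equals the harmonic identity wherever defined", {
  withr::local_seed(71)
  for (i in 1:20) {
    counts <- c(TP = sample(0:20, 1), FN = sample(0:20, 1),
                TN = sample(0:20, 1), FP = sample(0:20, 1))
    m <- compute_metrics(counts)
    if (!is.na(m$PRE) && !is.na(m$SN) && (m$PRE + m$SN) > 0) {
      expect_equal(m$F1, 2 * m$PRE * m$SN / (m$PRE + m$SN))
    }
  }
})

test_that("rank AUC equals the brute-force pairwise statistic, ties included", {
  withr::local_seed(73)
  for (i in 1:15) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, 0.5)
    if (sum(truth) == 0 || sum(truth) == n) truth[1:2] <- c(0, 1)
    scores <- round(runif(n), 1)   # heavy ties
    expect_equal(auc_score(scores, truth), brute_auc(scores, truth))
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(74)
  truth <- rbinom(150, 1, 0.4)
  truth[1:2] <- c(0, 1)
  scores <- rnorm(150) + truth
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_score(scores, truth), ref, tolerance = 1e-12)
})

test_that("stratified folds partition every sample once, reproducibly", {
  withr::local_seed(75)
  y <- rep(c("coding", "lncRNA"), times = c(60, 40))
  f1 <- stratified_folds(y, k = 10, seed = 5)
  f2 <- stratified_folds(y, k = 10, seed = 5)
  expect_identical(f1, f2)
  expect_true(all(f1 %in% 1:10))
  expect_equal(length(f1), 100)
  # stratification: each fold holds both classes
  for (k in 1:10) {
    expect_true(all(c("coding", "lncRNA") %in% y[f1 == k]))
  }
  expect_false(identical(f1, stratified_folds(y, k = 10, seed = 6)))
})

test_that("cross-validation drives fit/predict per fold and pools scores", {
  withr::local_seed(77)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- rep(c("coding", "lncRNA"), 100)
  # constant-score model: tie-averaged AUC is exactly 0.5
  cv <- cross_validate(X, y,
                       fit_fun = function(X, y) "const",
                       predict_fun = function(m, X) rep(0.5, nrow(X)),
                       folds = 5, seed = 3)
  expect_equal(cv$pooled$AUC, 0.5)
  expect_equal(nrow(cv$per_fold), 5)
  # every sample is tested exactly once
  expect_equal(sort(unique(cv$fold_ids)), 1:5)
  expect_equal(tabulate(cv$fold_ids), rep(40, 5))
  # reproducibility
  cv2 <- cross_validate(X, y, function(X, y) "const",
                        function(m, X) rep(0.5, nrow(X)), folds = 5, seed = 3)
  expect_identical(cv$fold_ids, cv2$fold_ids)
  expect_equal(cv$pooled, cv2$pooled)
})
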