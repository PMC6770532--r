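make_masks <- function(p, n_members, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_members), function(i) {
      g <- rbinom(p, 1, 0.5)
      if (sum(g) == 0) g[1] <- 1L
      as.integer(g)
    })
  })
}

test_that("the stack trains one forest per mask and rejects empty masks", {
  dat <- toy_feature_data(n = 100, p = 12, n_inf = 3, beta = 1.5, seed = 91)
  masks <- make_masks(12, 10)
  m <- train_stacked(dat$X, dat$y, masks, rf_trees = 30, seed = 2)
  expect_equal(m$n_members, 10)
  expect_equal(generics::glance(m)$n_members, 10)
  m2 <- train_stacked(dat$X, dat$y, masks[1:2], rf_trees = 30, seed = 2)
  expect_equal(m2$n_members, 2)
  expect_error(
    train_stacked(dat$X, dat$y, list(rep(0L, 12)), rf_trees = 10),
    "no features")
})

test_that("the output layer is the arithmetic mean of member probabilities", {
  dat <- toy_feature_data(n = 100, p = 12, n_inf = 3, beta = 1.5, seed = 93)
  masks <- make_masks(12, 4, seed = 3)
  m <- train_stacked(dat$X, dat$y, masks, rf_trees = 30, seed = 5)
  member_scores <- sapply(seq_along(masks), function(i) {
    mm <- m$members[[i]]
    predict(mm$fit, data = dat$X[, which(mm$mask == 1), drop = FALSE],
            num.threads = 1)$predictions[, "lncRNA"]
  })
  s <- predict_score(m, dat$X)
  expect_equal(s, rowMeans(member_scores))
  expect_true(all(s >= apply(member_scores, 1, min) - 1e-12))
  expect_true(all(s <= apply(member_scores, 1, max) + 1e-12))
})

test_that("training is reproducible under a fixed seed", {
  dat <- toy_feature_data(n = 80, p = 10, n_inf = 3, beta = 1.5, seed = 95)
  masks <- make_masks(10, 3, seed = 5)
  m1 <- train_stacked(dat$X, dat$y, masks, rf_trees = 40, seed = 8)
  m2 <- train_stacked(dat$X, dat$y, masks, rf_trees = 40, seed = 8)
  expect_identical(predict_score(m1, dat$X), predict_score(m2, dat$X))
})

test_that("label prediction thresholds scores with ties toward lncRNA", {
  dat <- toy_feature_data(n = 80, p = 10, n_inf = 3, beta = 1.5, seed = 97)
  masks <- make_masks(10, 3, seed = 7)
  m <- train_stacked(dat$X, dat$y, masks, rf_trees = 30, seed = 9)
  s <- predict_score(m, dat$X)
  expect_equal(as.character(predict_label(m, dat$X, threshold = 0)),
               rep("lncRNA", 80))  # every score >= 0
  expect_equal(as.character(predict_label(m, dat$X, threshold = 1.01)),
               rep("coding", 80))
  # monotone: raising the threshold never increases lncRNA calls
  counts <- sapply(c(0, 0.25, 0.5, 0.75, 1.01), function(t)
    sum(predict_label(m, dat$X, threshold = t) == "lncRNA"))
  expect_true(all(diff(counts) <= 0))
  # ties resolve toward lncRNA
  t_star <- s[5]
  expect_equal(as.character(predict_label(m, dat$X, threshold = t_star)[5]),
               "lncRNA")
  expect_equal(as.character(predict(m, dat$X, type = "label")),
               as.character(predict_label(m, dat$X)))
})

test_that("schema hashes guard prediction and model loading", {
  dat <- toy_feature_data(n = 80, p = 10, n_inf = 3, beta = 1.5, seed = 99)
  masks <- make_masks(10, 3, seed = 9)
  m <- train_stacked(dat$X, dat$y, masks, rf_trees = 30, seed = 10)
  Xbad <- dat$X
  colnames(Xbad)[1] <- "renamed"
  expect_error(predict_score(m, Xbad), "schema")

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict_score(back, dat$X), predict_score(m, dat$X))
  expect_equal(back$seed, m$seed)
  # tampered archive fails the hash check
  m$feature_names[1] <- "tampered"
  save_model(m, path)
  expect_error(load_model(path), "hash")
  saveRDS(42, path)
  expect_error(load_model(path), "stacked model")
})

test_that("averaging stabilizes scores relative to single members", {
  dat <- toy_feature_data(n = 120, p = 12, n_inf = 3, beta = 0.8, seed = 101)
  masks <- make_masks(12, 6, seed = 11)
  # bootstrap-retrain with different seeds; compare score variance across runs
  runs_ens <- sapply(1:5, function(r) {
    m <- train_stacked(dat$X, dat$y, masks, rf_trees = 20, seed = 100 + r)
    predict_score(m, dat$X)
  })
  runs_single <- sapply(1:5, function(r) {
    m <- train_stacked(dat$X, dat$y, masks[1], rf_trees = 20, seed = 100 + r)
    predict_score(m, dat$X)
  })
  expect_lte(mean(apply(runs_ens, 1, var)), mean(apply(runs_single, 1, var)))
})
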