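test_that("population initialization is seeded Bernoulli(0.5)", {
  cfg <- ga_desk_profile(seed = 9)
  p1 <- init_population(260, cfg)
  p2 <- init_population(260, cfg)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(60, 260))
  # total ones within 4 sigma of the binomial mean
  n <- length(p1)
  expect_lt(abs(sum(p1) - n / 2), 4 * sqrt(n * 0.25))
})

test_that("fitness is CV AUC of the masked forest, with declared degenerate rules", {
  dat <- toy_feature_data(n = 120, p = 8, n_inf = 1, beta = 50, seed = 81)
  cfg <- ga_config(pop_size = 10, generations = 2, cv_folds = 3,
                   rf_trees = 30, seed = 4, top_n = 2)
  expect_equal(ga_fitness(rep(0, 8), dat$X, dat$y, cfg), 0)
  # a perfect separator column yields AUC ~ 1
  mask <- c(1, rep(0, 7))
  expect_gte(ga_fitness(mask, dat$X, dat$y, cfg), 0.99)
})

test_that("a uniform population with no variation operators is a fixed point", {
  dat <- toy_feature_data(n = 60, p = 6, n_inf = 2, beta = 1.5, seed = 83)
  cfg <- ga_config(pop_size = 8, generations = 3, tournament_size = 3,
                   crossover_prob = 0, individual_mutation_prob = 0,
                   cv_folds = 3, rf_trees = 20, seed = 7, top_n = 2,
                   plateau_patience = 2)
  chrom <- c(1L, 1L, 0L, 0L, 1L, 0L)
  init <- matrix(rep(chrom, each = 8), nrow = 8)
  ga <- ga_select(dat$X, dat$y, cfg, init = init)
  expect_equal(length(ga$subsets), 1)   # one unique chromosome ever seen
  expect_equal(ga$subsets[[1]], chrom)
  expect_true(all(ga$log$best == ga$log$best[1]))
})

test_that("GA runs are bit-reproducible and externally verifiable", {
  dat <- toy_feature_data(n = 80, p = 10, n_inf = 3, beta = 1.2, seed = 85)
  cfg <- ga_config(pop_size = 10, generations = 4, cv_folds = 3,
                   rf_trees = 20, seed = 11, top_n = 4, plateau_patience = 3)
  ga1 <- ga_select(dat$X, dat$y, cfg)
  ga2 <- ga_select(dat$X, dat$y, cfg)
  expect_identical(ga1$subsets, ga2$subsets)
  expect_equal(ga1$log, ga2$log)
  expect_equal(ga1$fitness, ga2$fitness)
  # hall-of-fame fitness is sorted and nondecreasing over generations
  expect_true(all(diff(ga1$fitness) <= 0))
  expect_true(all(diff(ga1$log$best_ever) >= 0))
  # oracle equivalence: stored fitness is reproduced by an independent call
  expect_equal(ga_fitness(ga1$subsets[[1]], dat$X, dat$y, cfg),
               ga1$fitness[[1]])
})

test_that("decoding and subset intersection respect schema order", {
  nm <- feature_schema()$name
  expect_equal(decode_chromosome(rep(0, 260)), character(0))
  expect_length(decode_chromosome(rep(1, 260)), 260)
  g <- rep(0, 260); g[17] <- 1
  expect_equal(decode_chromosome(g), nm[17])
  expect_equal(subset_intersection(list(c("A", "C"), c("C", "A"))),
               c("A", "C"))
  expect_equal(subset_intersection(list("A", "T")), character(0))
  expect_equal(subset_intersection(list(c("A", "C", "G"), c("C", "G", "T"),
                                        "C")), "C")
})

test_that("GA results expose tidy, glance, report and plot views", {
  dat <- toy_feature_data(n = 60, p = 6, n_inf = 2, beta = 1.5, seed = 87)
  cfg <- ga_config(pop_size = 8, generations = 2, cv_folds = 3, rf_trees = 20,
                   seed = 13, top_n = 3, plateau_patience = 2)
  ga <- ga_select(dat$X, dat$y, cfg)
  td <- generics::tidy(ga)
  expect_equal(names(td), c("rank", "fitness", "n_features"))
  expect_equal(nrow(td), length(ga$subsets))
  gl <- generics::glance(ga)
  expect_equal(gl$best_fitness, max(ga$fitness))
  expect_s3_class(ggplot2::autoplot(ga), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  write_ga_report(ga, path)
  rep <- jsonlite::read_json(path)
  expect_equal(length(rep$subsets), length(ga$subsets))
  expect_equal(rep$config$seed, 13)
})
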