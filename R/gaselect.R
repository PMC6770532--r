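#' Genetic-algorithm configuration
#'
#' Hyperparameters of the GA-RF feature-selection algorithm. The defaults are
#' the full-scale settings: a population of 500 binary chromosomes evolved for
#' up to 50 generations with tournament selection of size 3, single-point
#' crossover with probability 0.5, per-individual mutation probability 0.2
#' with per-gene flip probability 0.05, and a fitness equal to the 10-fold
#' cross-validated AUC of a 100-tree random forest restricted to the selected
#' features. [ga_desk_profile()] is a scaled-down profile for interactive use
#' and tests.
#'
#' @param pop_size Population size.
#' @param generations Maximum number of generations.
#' @param tournament_size Tournament size for selection.
#' @param crossover_prob Probability that a consecutive pair of selected
#'   parents is recombined by single-point crossover.
#' @param gene_flip_prob Per-gene flip probability within a mutating
#'   individual.
#' @param individual_mutation_prob Probability that an offspring mutates.
#' @param rf_trees Trees per random forest in the fitness evaluation.
#' @param cv_folds Cross-validation folds in the fitness evaluation.
#' @param seed Integer seed controlling the whole run.
#' @param top_n Number of best-ever chromosomes returned.
#' @param plateau_patience Early stop after this many consecutive generations
#'   without a best-ever fitness improvement greater than 1e-4.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 500, generations = 50, tournament_size = 3,
                      crossover_prob = 0.5, gene_flip_prob = 0.05,
                      individual_mutation_prob = 0.2, rf_trees = 100,
                      cv_folds = 10, seed = 1, top_n = 10,
                      plateau_patience = 5) {
  cfg <- list(pop_size = pop_size, generations = generations,
              tournament_size = tournament_size,
              crossover_prob = crossover_prob,
              gene_flip_prob = gene_flip_prob,
              individual_mutation_prob = individual_mutation_prob,
              rf_trees = rf_trees, cv_folds = cv_folds, seed = seed,
              top_n = top_n, plateau_patience = plateau_patience)
  stopifnot(cfg$pop_size >= cfg$top_n, cfg$cv_folds >= 2,
            cfg$crossover_prob >= 0, cfg$crossover_prob <= 1,
            cfg$gene_flip_prob >= 0, cfg$gene_flip_prob <= 1,
            cfg$individual_mutation_prob >= 0,
            cfg$individual_mutation_prob <= 1)
  structure(cfg, class = "ga_config")
}

#' @rdname ga_config
#' @param ... Overrides passed on to [ga_config()].
#' @export
ga_desk_profile <- function(...) {
  args <- list(pop_size = 60, generations = 25, cv_folds = 5, rf_trees = 50)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(ga_config, args)
}

#' Initialize a GA population
#'
#' Each gene of each chromosome is drawn i.i.d. Bernoulli(0.5).
#'
#' @param n_genes Chromosome length (number of candidate features).
#' @param cfg A `ga_config`.
#' @return A `pop_size` x `n_genes` 0/1 integer matrix.
#' @export
init_population <- function(n_genes, cfg) {
  with_seed(cfg$seed, {
    matrix(as.integer(stats::runif(cfg$pop_size * n_genes) < 0.5),
           nrow = cfg$pop_size, ncol = n_genes)
  })
}

# Single fitness evaluation: stratified cv_folds-fold CV AUC of a random
# forest on the masked columns. `fold_ids` is fixed for the whole GA run so
# chromosomes are compared on identical splits. The all-zero chromosome has
# fitness 0 by definition.
fitness_masked <- function(genes, X, y, cfg, fold_ids, rf_seed) {
  cols <- which(genes == 1L)
  if (length(cols) == 0) return(0)
  Xm <- X[, cols, drop = FALSE]
  aucs <- numeric(cfg$cv_folds)
  for (f in seq_len(cfg$cv_folds)) {
    test <- fold_ids == f
    fit <- ranger::ranger(x = Xm[!test, , drop = FALSE], y = y[!test],
                          num.trees = cfg$rf_trees, probability = TRUE,
                          num.threads = 1, seed = rf_seed + f,
                          verbose = FALSE)
    p <- stats::predict(fit, data = Xm[test, , drop = FALSE],
                        num.threads = 1)$predictions[, "lncRNA"]
    aucs[f] <- auc_score(p, y[test])
  }
  mean(aucs)
}

#' Fitness of a single chromosome
#'
#' The cross-validated AUC of a random forest restricted to the features the
#' chromosome selects, using a seeded stratified fold split. This is the same
#' computation the GA performs internally, exposed for inspection.
#'
#' @param genes 0/1 vector over the feature columns of `X`.
#' @param X Feature matrix or feature tibble.
#' @param y Labels (lncRNA positive).
#' @param cfg A `ga_config`.
#' @return AUC in \[0, 1\] (0 for the all-zero chromosome).
#' @export
ga_fitness <- function(genes, X, y, cfg = ga_desk_profile()) {
  if (is.data.frame(X)) X <- feature_matrix(X, schema_names = NULL)
  y <- as_label_factor(y)
  fold_ids <- stratified_folds(y, k = cfg$cv_folds, seed = cfg$seed)
  fitness_masked(as.integer(genes), X, y, cfg, fold_ids, rf_seed = cfg$seed)
}

#' GA-RF feature selection
#'
#' Evolves binary feature masks to maximize the cross-validated AUC of a
#' random forest restricted to the masked features, and returns the `top_n`
#' best unique chromosomes ever evaluated (the hall of fame). Selection is by
#' size-`tournament_size` tournaments, recombination by single-point
#' crossover, mutation by per-gene bit flips. The run stops early when the
#' best-ever fitness has not improved by more than 1e-4 for
#' `plateau_patience` consecutive generations. Fitness values are cached by
#' chromosome, and the whole run is reproducible from `cfg$seed`.
#'
#' @param X Feature matrix or feature tibble (columns are candidate features).
#' @param y Labels (lncRNA positive).
#' @param cfg A `ga_config`; see [ga_desk_profile()] for the scaled-down
#'   profile.
#' @param init Optional initial population (a `pop_size` x `n_genes` 0/1
#'   matrix); by default genes are drawn i.i.d. Bernoulli(0.5) from the seed.
#' @return An object of class `lnc_ga`: list with `subsets` (list of `top_n`
#'   0/1 gene vectors, best first), `fitness` (their AUCs), `hall` (tibble
#'   with rank, fitness, n_features), `log` (per-generation best/mean/
#'   best-ever fitness), `feature_names`, `config`, `n_evaluations`.
#' @export
ga_select <- function(X, y, cfg = ga_config(), init = NULL) {
  if (is.data.frame(X)) X <- feature_matrix(X, schema_names = NULL)
  feature_names <- colnames(X)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2) rlang::abort("labels contain a single class")
  n_genes <- ncol(X)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fold_ids <- stratified_folds(y, k = cfg$cv_folds, seed = cfg$seed)
  evaluate <- function(genes, rf_seed) {
    key <- paste(genes, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- fitness_masked(genes, X, y, cfg, fold_ids, rf_seed)
    cache[[key]] <- val
    n_eval <<- n_eval + 1L
    val
  }

  # hall of fame: best top_n unique chromosomes ever evaluated
  hall <- list()   # each: list(key, genes, fitness)
  update_hall <- function(genes, fit) {
    key <- paste(genes, collapse = "")
    if (any(vapply(hall, function(h) h$key == key, logical(1)))) return()
    hall[[length(hall) + 1]] <<- list(key = key, genes = genes, fitness = fit)
    ord <- order(vapply(hall, `[[`, numeric(1), "fitness"), decreasing = TRUE)
    hall <<- hall[ord[seq_len(min(cfg$top_n, length(hall)))]]
  }

  log_rows <- list()
  with_seed(cfg$seed, {
    pop <- if (is.null(init)) {
      matrix(as.integer(stats::runif(cfg$pop_size * n_genes) < 0.5),
             nrow = cfg$pop_size, ncol = n_genes)
    } else {
      stopifnot(nrow(init) == cfg$pop_size, ncol(init) == n_genes)
      init
    }
    # same RF seed convention as ga_fitness(): any returned fitness can be
    # reproduced by an independent ga_fitness() call with the same config
    rf_seed_base <- cfg$seed
    fits <- numeric(cfg$pop_size)
    for (i in seq_len(cfg$pop_size)) {
      fits[i] <- evaluate(pop[i, ], rf_seed_base)
      update_hall(pop[i, ], fits[i])
    }
    best_ever <- max(fits)
    stale <- 0L
    gen <- 0L
    log_rows[[1]] <- tibble::tibble(generation = 0L, best = max(fits),
                                    mean = mean(fits), best_ever = best_ever)
    while (gen < cfg$generations) {
      gen <- gen + 1L
      # tournament selection
      sel_idx <- vapply(seq_len(cfg$pop_size), function(i) {
        cand <- sample.int(cfg$pop_size, cfg$tournament_size, replace = TRUE)
        cand[which.max(fits[cand])]
      }, integer(1))
      offspring <- pop[sel_idx, , drop = FALSE]
      # single-point crossover on consecutive pairs
      for (i in seq(1, cfg$pop_size - 1, by = 2)) {
        if (stats::runif(1) < cfg$crossover_prob && n_genes >= 2) {
          pt <- sample.int(n_genes - 1L, 1)
          tail_a <- offspring[i, (pt + 1L):n_genes]
          offspring[i, (pt + 1L):n_genes] <- offspring[i + 1L, (pt + 1L):n_genes]
          offspring[i + 1L, (pt + 1L):n_genes] <- tail_a
        }
      }
      # flip-bit mutation
      for (i in seq_len(cfg$pop_size)) {
        if (stats::runif(1) < cfg$individual_mutation_prob) {
          flips <- stats::runif(n_genes) < cfg$gene_flip_prob
          offspring[i, flips] <- 1L - offspring[i, flips]
        }
      }
      pop <- offspring
      for (i in seq_len(cfg$pop_size)) {
        fits[i] <- evaluate(pop[i, ], rf_seed_base)
        update_hall(pop[i, ], fits[i])
      }
      new_best <- max(best_ever, max(fits))
      improved <- (new_best - best_ever) > 1e-4
      best_ever <- new_best
      stale <- if (improved) 0L else stale + 1L
      log_rows[[length(log_rows) + 1]] <-
        tibble::tibble(generation = gen, best = max(fits), mean = mean(fits),
                       best_ever = best_ever)
      if (stale >= cfg$plateau_patience) break
    }
  })

  hall_fit <- vapply(hall, `[[`, numeric(1), "fitness")
  structure(
    list(subsets = lapply(hall, `[[`, "genes"),
         fitness = hall_fit,
         hall = tibble::tibble(
           rank = seq_along(hall), fitness = hall_fit,
           n_features = vapply(hall, function(h) sum(h$genes), numeric(1))
         ),
         log = dplyr::bind_rows(log_rows),
         feature_names = feature_names,
         config = cfg,
         n_evaluations = n_eval),
    class = "lnc_ga"
  )
}

#' Decode a chromosome into feature names
#'
#' @param genes 0/1 gene vector.
#' @param feature_names Names of the candidate features, in schema order
#'   (defaults to the 260-feature schema).
#' @return Character vector of selected feature names.
#' @export
decode_chromosome <- function(genes, feature_names = feature_schema()$name) {
  stopifnot(length(genes) == length(feature_names))
  feature_names[genes == 1]
}

#' Intersection of feature subsets
#'
#' The features present in every one of the supplied subsets, returned in
#' schema order.
#'
#' @param subsets A list of character vectors of feature names.
#' @param feature_names Reference ordering (defaults to the schema).
#' @return Character vector of the common features.
#' @export
subset_intersection <- function(subsets, feature_names = feature_schema()$name) {
  common <- Reduce(intersect, subsets)
  feature_names[feature_names %in% common]
}

#' Write a GA selection report as JSON
#'
#' Records the configuration (including the seed), the per-generation fitness
#' log, and the decoded subsets with their fitness values.
#'
#' @param ga An `lnc_ga` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ga_report <- function(ga, path) {
  report <- list(
    config = unclass(ga$config),
    n_evaluations = ga$n_evaluations,
    log = ga$log,
    subsets = lapply(seq_along(ga$subsets), function(i) {
      list(rank = i, fitness = ga$fitness[[i]],
           features = decode_chromosome(ga$subsets[[i]], ga$feature_names))
    })
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.lnc_ga <- function(x, ...) {
  cat(sprintf(
    "GA-RF feature selection: %d subsets kept (fitness %.4f..%.4f), %d generations, %d evaluations\n",
    length(x$subsets), max(x$fitness), min(x$fitness),
    max(x$log$generation), x$n_evaluations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the hall of fame of a GA run
#'
#' @param x An `lnc_ga` object.
#' @param ... Unused.
#' @return A tibble with one row per returned subset: `rank`, `fitness`,
#'   `n_features`.
#' @method tidy lnc_ga
#' @export
tidy.lnc_ga <- function(x, ...) {
  x$hall
}

#' One-row summary of a GA run
#'
#' @param x An `lnc_ga` object.
#' @param ... Unused.
#' @return A one-row tibble: `generations_run`, `n_evaluations`,
#'   `best_fitness`, `converged` (TRUE when the run stopped before the
#'   generation cap).
#' @method glance lnc_ga
#' @export
glance.lnc_ga <- function(x, ...) {
  tibble::tibble(
    generations_run = max(x$log$generation),
    n_evaluations = x$n_evaluations,
    best_fitness = max(x$fitness),
    converged = max(x$log$generation) < x$config$generations
  )
}

#' Fitness-trace plot of a GA run
#'
#' @param object An `lnc_ga` object.
#' @param ... Unused.
#' @return A ggplot object showing per-generation best, mean and best-ever
#'   fitness.
#' @method autoplot lnc_ga
#' @export
autoplot.lnc_ga <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("best", "mean", "best_ever"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "CV AUC fitness", colour = NULL,
                  title = "GA-RF fitness trace") +
    ggplot2::theme_minimal()
}
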