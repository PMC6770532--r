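# Independent brute-force oracles and small data helpers used across tests.

# Brute-force ORF enumeration: scan every position for ATG and walk codon by
# codon to the first stop; written with plain string ops, independent of the
# package's vectorized scanner.
brute_orfs <- function(seq) {
  L <- nchar(seq)
  rows <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (a in seq_len(max(L - 2, 0))) {
    if (substr(seq, a, a + 2) != "ATG") next
    end <- NA
    has_stop <- FALSE
    j <- a + 3
    while (j + 2 <= L) {
      if (substr(seq, j, j + 2) %in% stops) {
        end <- j + 2
        has_stop <- TRUE
        break
      }
      j <- j + 3
    }
    if (!has_stop) end <- a - 1 + 3 * ((L - a + 1) %/% 3)
    rows[[length(rows) + 1]] <- data.frame(
      frame = (a - 1) %% 3, start = a - 1, end = end,
      length = end - (a - 1), has_stop = has_stop)
  }
  if (length(rows) == 0) {
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      length = integer(), has_stop = logical()))
  }
  do.call(rbind, rows)
}

# Random DNA string of length n from the current RNG.
rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# All sequences of length n over an alphabet (for exhaustive enumeration).
enumerate_seqs <- function(n, alphabet) {
  out <- alphabet
  while (n > 1) {
    out <- as.vector(outer(out, alphabet, paste0))
    n <- n - 1
  }
  out
}

# Pairwise-AUC oracle: fraction of positive/negative pairs ranked correctly,
# ties counted half.
brute_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Small separable feature matrix for GA / ensemble tests: `n_inf` columns
# carry the label signal, the rest are noise.
toy_feature_data <- function(n = 200, p = 20, n_inf = 5, beta = 0.8,
                             seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(stats::rnorm(n * p), n, p)
    for (j in seq_len(n_inf)) X[, j] <- X[, j] + beta * y
    colnames(X) <- sprintf("f%02d", seq_len(p))
    list(X = X, y = ifelse(y == 1, "lncRNA", "coding"))
  })
}

# Tiny trained hexamer table (deterministic).
tiny_hexamer_table <- function(seed = 11) {
  withr::with_seed(seed, {
    coding <- replicate(5, paste0("ATG", rand_dna(60, c("G", "A", "C")), "TAA"))
    noncoding <- replicate(5, rand_dna(66))
    train_hexamer_table(coding, noncoding)
  })
}
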