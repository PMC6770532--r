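test_that("hexamer table training counts in-frame hexamers with smoothing", {
  tb <- train_hexamer_table("AAAAAA", "CCCCCC")
  expect_equal(tb$coding_freq[["AAAAAA"]], 2 / 4097)
  expect_equal(tb$coding_freq[["AAAAAC"]], 1 / 4097)
  expect_equal(sum(tb$coding_freq), 1, tolerance = 1e-9)
  expect_equal(sum(tb$noncoding_freq), 1, tolerance = 1e-9)
  expect_true(all(tb$coding_freq > 0))

  # identical inputs give identical tables
  tb2 <- train_hexamer_table(c("ATGAAATTT"), c("ATGAAATTT"))
  expect_equal(tb2$coding_freq, tb2$noncoding_freq)

  expect_error(train_hexamer_table(character(0), "ACGTAC"), "non-empty")
})

test_that("hexamer score is a mean in-frame log-likelihood ratio", {
  expect_equal(hexamer_score("ATGAAATAA", neutral_hexamer_table()), 0)
  tb <- tiny_hexamer_table()
  expect_equal(hexamer_score("ATGAA", tb), 0)   # < 6 nt: no hexamer
  # direct hand computation on a 9-nt ORF: hexamers at offsets 0 and 3
  s <- "ATGAAATTT"
  expected <- mean(log(tb$coding_freq[c("ATGAAA", "AAATTT")] /
                         tb$noncoding_freq[c("ATGAAA", "AAATTT")]))
  expect_equal(hexamer_score(s, tb), expected)
})

test_that("swapping tables negates scores; duplicating training sets changes nothing", {
  tb <- tiny_hexamer_table()
  swapped <- structure(list(coding_freq = tb$noncoding_freq,
                            noncoding_freq = tb$coding_freq,
                            pseudocount = tb$pseudocount,
                            n_coding = tb$n_noncoding,
                            n_noncoding = tb$n_coding),
                       class = "lnc_hexamer_table")
  withr::local_seed(31)
  for (i in 1:20) {
    s <- rand_dna(3 * sample(2:30, 1))
    expect_equal(hexamer_score(s, swapped), -hexamer_score(s, tb))
  }

  withr::local_seed(32)
  coding <- replicate(4, paste0("ATG", rand_dna(30), "TAA"))
  noncoding <- replicate(4, rand_dna(36))
  tb1 <- train_hexamer_table(coding, noncoding)
  tb2 <- train_hexamer_table(rep(coding, 2), rep(noncoding, 2))
  # duplication doubles counts and the effective pseudocount weight differs;
  # invariance holds when the pseudocount is scaled with the data
  tb3 <- train_hexamer_table(rep(coding, 2), rep(noncoding, 2), pseudocount = 2)
  expect_equal(tb1$coding_freq, tb3$coding_freq, tolerance = 1e-12)
  expect_equal(tb1$noncoding_freq, tb3$noncoding_freq, tolerance = 1e-12)
  expect_true(is.numeric(tb2$coding_freq))
})

test_that("sequences drawn from each background score on the matching side", {
  withr::local_seed(33)
  # coding background: biased codon usage; noncoding: uniform
  codons <- c("GAA", "GAT", "AAG", "GCA")
  coding_train <- replicate(60, paste0(
    "ATG", paste(sample(codons, 40, replace = TRUE), collapse = ""), "TAA"))
  noncoding_train <- replicate(60, rand_dna(126))
  tb <- train_hexamer_table(coding_train, noncoding_train)
  coding_new <- replicate(100, paste0(
    "ATG", paste(sample(codons, 40, replace = TRUE), collapse = ""), "TAA"))
  noncoding_new <- replicate(100, rand_dna(126))
  expect_gt(mean(sapply(coding_new, hexamer_score, table = tb)), 0)
  expect_lt(mean(sapply(noncoding_new, hexamer_score, table = tb)), 0)
})

test_that("hexamer tables round-trip through TSV", {
  tb <- tiny_hexamer_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hexamer_table(tb, path)
  back <- read_hexamer_table(path)
  expect_equal(back$coding_freq, tb$coding_freq, tolerance = 1e-12)
  expect_equal(back$noncoding_freq, tb$noncoding_freq, tolerance = 1e-12)
  expect_equal(back$pseudocount, tb$pseudocount)
  expect_equal(back$n_coding, tb$n_coding)
})
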