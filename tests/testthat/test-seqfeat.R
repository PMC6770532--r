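test_that("stop-codon block matches hand counts and the per-frame variance", {
  expect_equal(unname(stop_codon_block("TAATAA")), c(2, 1, 8 / 9, 2 / 9))
  expect_equal(unname(stop_codon_block("AAAAAA")), c(0, 0, 0, 0))
  b <- stop_codon_block("TAGTAGTAG")
  expect_equal(b[["stop_codon_count"]], 3)
  expect_equal(b[["stop_codon_freq"]], 1)
})

test_that("stop-codon and GC blocks agree with exhaustive enumeration oracles", {
  stops <- c("TAA", "TAG", "TGA")
  for (n in c(3, 5, 7)) {
    for (s in enumerate_seqs(n, c("A", "T", "G"))) {
      # oracle: count stops per frame with explicit substring loops
      counts <- freqs <- numeric(3)
      for (f in 0:2) {
        starts <- if (f + 1 <= n - 2) seq(f + 1, n - 2, by = 3) else integer(0)
        starts <- starts[starts + 2 <= n]
        codons <- if (length(starts)) substring(s, starts, starts + 2) else
          character(0)
        counts[f + 1] <- sum(codons %in% stops)
        freqs[f + 1] <- if (length(codons)) counts[f + 1] / length(codons) else 0
      }
      pv <- function(x) mean((x - mean(x))^2)
      expect_equal(unname(stop_codon_block(s)),
                   c(counts[1], freqs[1], pv(counts), pv(freqs)), info = s)
      # whole-transcript GC oracle
      ch <- strsplit(s, "")[[1]]
      expect_equal(gc_block(s, orf_profile(s))[["GC_content"]],
                   sum(ch %in% c("G", "C")) / n, info = s)
    }
  }
})

test_that("position-frequency block computes Fickett position asymmetry", {
  expect_equal(unname(position_frequency_block("ATGATGATG")), c(3, 0, 3, 3))
  expect_equal(unname(position_frequency_block("AAAAAAAAA")), c(0.75, 0, 0, 0))
})

test_that("Fickett score reproduces an independent lookup-pipeline evaluation", {
  # fixed 60-nt sequence; expected value computed by an explicit step-by-step
  # walk through the published tables, independent of the package pipeline
  s <- "ATGGACGAAACGATGGACGAAACGATGGACGAAACGATGGACGAAACGATGGACGAAACG"
  tabs <- lncstack:::.fickett
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(s, "")[[1]]
  expected <- 0
  for (i in 1:4) {
    b <- bases[i]
    at_pos <- sapply(1:3, function(p) {
      idx <- seq(p, length(ch), by = 3)
      sum(ch[idx] == b)
    })
    posv <- max(at_pos) / (min(at_pos) + 1)
    contv <- sum(ch == b) / length(ch)
    ppick <- tabs$position_prob[[b]][min(which(posv >= tabs$position_para))]
    cpick <- tabs$content_prob[[b]][min(which(contv >= tabs$content_para))]
    expected <- expected + tabs$position_weight[[b]] * ppick +
      tabs$content_weight[[b]] * cpick
  }
  expect_equal(fickett_score(s), expected)

  # bound forced by the lookup ranges
  withr::local_seed(5)
  for (i in 1:20) {
    sc <- fickett_score(rand_dna(90))
    expect_gte(sc, sum(unlist(lapply(bases, function(b)
      tabs$position_weight[[b]] * min(tabs$position_prob[[b]]) +
        tabs$content_weight[[b]] * min(tabs$content_prob[[b]])))))
    expect_lte(sc, sum(unlist(lapply(bases, function(b)
      tabs$position_weight[[b]] * max(tabs$position_prob[[b]]) +
        tabs$content_weight[[b]] * max(tabs$content_prob[[b]])))))
  }
})

test_that("codon-periodic sequences outscore uniform ones on Fickett and SNR", {
  withr::local_seed(7)
  n <- 120
  periodic <- replicate(100, {
    codons <- sample(c("ATG", "GAC", "GAA", "ACG"), n / 3, replace = TRUE,
                     prob = c(0.5, 0.3, 0.1, 0.1))
    paste(codons, collapse = "")
  })
  uniform <- replicate(100, rand_dna(n))
  expect_gt(mean(sapply(periodic, fickett_score)),
            mean(sapply(uniform, fickett_score)))
  expect_gt(mean(sapply(periodic, snr)), stats::median(sapply(uniform, snr)))
})

test_that("GC block covers ORF, fallback and UTR paths", {
  b <- gc_block("ATGC", orf_profile("ATGC"))
  expect_equal(unname(b[c("GC_content", "GC1", "GC2", "GC3")]),
               c(0.5, 0, 0, 1))
  expect_equal(unname(gc_block(strrep("A", 30), orf_profile(strrep("A", 30)))),
               rep(0, 7))
  # codons ATG, GGG, TAA: third positions are G, G, A
  b3 <- gc_block("ATGGGGTAA", orf_profile("ATGGGGTAA"))
  expect_equal(b3[["GC_content"]], 4 / 9)
  expect_equal(unname(b3[c("GC1", "GC2", "GC3")]), c(1 / 3, 1 / 3, 2 / 3))
  expect_equal(b3[["GC_frame_score"]], lncstack:::pop_var(c(1, 1, 2) / 3))
})

test_that("k-mer frequencies are normalized, ordered, and N-window-safe", {
  b <- kmer_block("AAAA")
  expect_equal(b[["A"]], 1)
  expect_equal(b[["AA"]], 1)
  expect_equal(b[["AAA"]], 1)
  expect_equal(sum(b[1:84] > 0), 3)
  expect_true(all(b[85:168] == 0))   # no ORF side

  b2 <- kmer_block("ACGT", "ACGT")
  expect_equal(unname(b2[c("A", "C", "G", "T")]), rep(0.25, 4))
  expect_equal(unname(b2[c("ORF_k_mer_A", "ORF_k_mer_C")]), c(0.25, 0.25))

  withr::local_seed(9)
  for (i in 1:10) {
    s <- rand_dna(50, c("A", "C", "G", "T", "N"))
    b3 <- kmer_block(s)
    for (k in 1:3) {
      idx <- switch(k, 1:4, 5:20, 21:84)
      expect_equal(sum(b3[idx]), 1, tolerance = 1e-12)
    }
  }
})

test_that("CTD distribution descriptors are occurrence quantile positions", {
  d <- ctd_distribution("ACGT")
  expect_equal(unname(d[1:5]), rep(0.25, 5))
  expect_equal(unname(d[6:10]), rep(0.5, 5))
  expect_equal(unname(d[11:15]), rep(0.75, 5))
  expect_equal(unname(d[16:20]), rep(1, 5))

  d2 <- ctd_distribution("AAAA")
  expect_equal(unname(d2[1:5]), c(0.25, 0.25, 0.5, 0.75, 1))
  expect_true(all(d2[6:20] == 0))

  withr::local_seed(13)
  for (i in 1:10) {
    d3 <- ctd_distribution(rand_dna(37))
    expect_true(all(d3 >= 0 & d3 <= 1))
    for (bidx in 0:3) {
      expect_true(!is.unsorted(d3[bidx * 5 + 1:5]))
    }
  }
})

test_that("entropy density profiles normalize and handle degeneracy", {
  expect_equal(unname(edp_profile(rep(3, 16))), rep(1 / 16, 16))
  onehot <- c(5, rep(0, 7))
  expect_equal(unname(edp_profile(onehot)), c(1, rep(0, 7)))
  withr::local_seed(17)
  for (i in 1:10) {
    cnt <- rpois(20, 4)
    if (sum(cnt) == 0) cnt[1] <- 1
    expect_equal(sum(edp_profile(cnt)), 1, tolerance = 1e-12)
  }
  expect_error(edp_profile(rep(0, 4)), "positive count")
})

test_that("SNR follows the declared spectral convention", {
  expect_equal(snr("ATGATGATGATG"), 5.5)
  expect_equal(snr(strrep("A", 30)), 0)
  expect_equal(snr("ACGTA"), 0)   # below minimum length
  # invariance under base relabeling
  withr::local_seed(21)
  s <- rand_dna(101)
  expect_equal(snr(s), snr(chartr("ACGT", "GTAC", s)), tolerance = 1e-9)
})

test_that("period-3 signals exceed i.i.d. background SNR", {
  withr::local_seed(23)
  n <- 300
  iid <- replicate(200, snr(rand_dna(n)))
  strict <- snr(strrep("ATG", n / 3))
  expect_gt(strict, stats::median(iid))
})

test_that("UTR coverage reflects the longest-ORF flanks", {
  expect_equal(unname(utr_coverage(orf_profile("ATGAAATAA"))), c(0, 0))
  expect_equal(unname(utr_coverage(orf_profile("CCCATGAAATAA"))), c(0.25, 0))
  expect_equal(unname(utr_coverage(orf_profile(strrep("C", 20)))), c(0, 0))
})
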