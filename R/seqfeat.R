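#' Stop-codon feature block
#'
#' Counts in-frame stop codons (`TAA`, `TAG`, `TGA`) in each of the three
#' forward reading frames (complete codons only). Returns the frame-0 count
#' and frequency together with the population variance of the counts and of
#' the frequencies across the three frames (the "frame scores").
#'
#' @param seq A normalized DNA sequence string.
#' @return Named numeric vector: `stop_codon_count`, `stop_codon_freq`,
#'   `stop_codon_frame_score`, `stop_codon_freq_frame_score`.
#' @examples
#' stop_codon_block("TAATAA")
#' @export
stop_codon_block <- function(seq) {
  if (nchar(seq) < 3) {
    return(c(stop_codon_count = 0, stop_codon_freq = 0,
             stop_codon_frame_score = 0, stop_codon_freq_frame_score = 0))
  }
  counts <- freqs <- numeric(3)
  for (f in 0:2) {
    codons <- frame_codons(seq, f)
    counts[f + 1] <- sum(codons %in% .stop_codons)
    freqs[f + 1] <- if (length(codons)) counts[f + 1] / length(codons) else 0
  }
  c(stop_codon_count = counts[1], stop_codon_freq = freqs[1],
    stop_codon_frame_score = pop_var(counts),
    stop_codon_freq_frame_score = pop_var(freqs))
}

# Per-base counts at the three codon positions, reading the whole sequence
# as frame-0 codons (complete codons only). Returns a 4x3 matrix (ACGT rows).
codon_position_counts <- function(codons) {
  m <- matrix(0, nrow = 4, ncol = 3, dimnames = list(.dna_bases, NULL))
  if (length(codons) == 0) return(m)
  for (p in 1:3) {
    tab <- table(factor(substr(codons, p, p), levels = .dna_bases))
    m[, p] <- as.numeric(tab)
  }
  m
}

#' Nucleotide position-frequency block
#'
#' Fickett's position parameter for each base: the asymmetry of base usage
#' across the three codon positions, `max(c1,c2,c3) / (min(c1,c2,c3) + 1)`,
#' computed over the whole transcript read as frame-0 codons.
#'
#' @param seq A normalized DNA sequence string.
#' @return Named numeric vector `A_pos_fickett`, `C_pos_fickett`,
#'   `G_pos_fickett`, `T_pos_fickett`.
#' @export
position_frequency_block <- function(seq) {
  out <- c(A_pos_fickett = 0, C_pos_fickett = 0,
           G_pos_fickett = 0, T_pos_fickett = 0)
  if (nchar(seq) < 3) return(out)
  m <- codon_position_counts(frame_codons(seq, 0L))
  vals <- apply(m, 1, function(cc) max(cc) / (min(cc) + 1))
  out[] <- vals
  out
}

# Piecewise lookup: first threshold that `value` meets selects the
# corresponding probability (the final threshold of 0 always matches).
fickett_lookup <- function(value, paras, probs) {
  probs[[which(value >= paras)[1]]]
}

#' Fickett TESTCODE score
#'
#' The classic TESTCODE statistic: the four base position parameters and the
#' four base composition fractions are each mapped to a probability through
#' Fickett's published lookup tables, and the eight probabilities are combined
#' as a weighted sum. Coding sequences tend to score higher than noncoding
#' ones because codon structure makes base usage position-asymmetric.
#'
#' @param seq A normalized DNA sequence string (length >= 3).
#' @return A single numeric score.
#' @export
fickett_score <- function(seq) {
  if (nchar(seq) < 3) return(0)
  m <- codon_position_counts(frame_codons(seq, 0L))
  pos_par <- apply(m, 1, function(cc) max(cc) / (min(cc) + 1))
  ch <- seq_chars(seq)
  base_counts <- as.numeric(table(factor(ch, levels = .dna_bases)))
  denom <- sum(base_counts)
  content_par <- if (denom > 0) base_counts / denom else rep(0, 4)
  score <- 0
  for (i in seq_along(.dna_bases)) {
    b <- .dna_bases[[i]]
    score <- score +
      .fickett$position_weight[[b]] *
        fickett_lookup(pos_par[[i]], .fickett$position_para, .fickett$position_prob[[b]]) +
      .fickett$content_weight[[b]] *
        fickett_lookup(content_par[[i]], .fickett$content_para, .fickett$content_prob[[b]])
  }
  unname(score)
}

# GC fraction of a string interval [lo, hi) (0-based half-open); 0 when empty.
gc_fraction <- function(seq, lo, hi) {
  if (hi <= lo) return(0)
  sub <- seq_chars(substr(seq, lo + 1L, hi))
  sum(sub == "G" | sub == "C") / length(sub)
}

#' GC-content feature block
#'
#' Whole-transcript GC content, GC at the three codon positions of the longest
#' ORF (`GC1`, `GC2`, `GC3`; when no ORF exists they are computed over the
#' frame-0 codons of the whole transcript), the GC frame score (population
#' variance of GC1..GC3), and the GC content of the 5' and 3' UTRs flanking
#' the longest ORF.
#'
#' @param seq A normalized DNA sequence string.
#' @param profile An `lnc_orf_profile` from [orf_profile()].
#' @return Named numeric vector: `GC_content`, `GC1`, `GC2`, `GC3`, `GC_frame_score`,
#'   `UTR5_GC`, `UTR3_GC`.
#' @export
gc_block <- function(seq, profile) {
  L <- nchar(seq)
  gc_all <- if (L > 0) gc_fraction(seq, 0L, L) else 0
  codons <- if (!is.null(profile$longest_orf)) {
    frame_codons(orf_subseq(seq, profile$longest_orf), 0L)
  } else {
    frame_codons(seq, 0L)
  }
  gc123 <- numeric(3)
  if (length(codons)) {
    for (p in 1:3) {
      bases <- substr(codons, p, p)
      gc123[p] <- sum(bases == "G" | bases == "C") / length(bases)
    }
  }
  c(GC_content = gc_all, GC1 = gc123[1], GC2 = gc123[2], GC3 = gc123[3],
    GC_frame_score = pop_var(gc123),
    UTR5_GC = gc_fraction(seq, profile$utr5[1], profile$utr5[2]),
    UTR3_GC = gc_fraction(seq, profile$utr3[1], profile$utr3[2]))
}

# k-mer frequencies of one sequence for a single k; windows containing N are
# excluded from both numerator and denominator.
kmer_freq <- function(seq, k, prefix = "") {
  kmers <- all_kmers(k)
  out <- stats::setNames(numeric(length(kmers)), paste0(prefix, kmers))
  if (nchar(seq) >= k) {
    counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), k)
    total <- sum(counts)
    if (total > 0) out[] <- as.numeric(counts[kmers]) / total
  }
  out
}

#' k-mer frequency block
#'
#' Frequencies of all 1-, 2-, and 3-mers (lexicographic order, A<C<G<T) over
#' the transcript and, separately, over its longest ORF subsequence: 84 + 84 =
#' 168 values. Windows containing `N` are skipped; each k-group sums to 1 when
#' at least one valid window exists. ORF-side values are all zero when the
#' transcript has no ORF.
#'
#' @param seq A normalized DNA sequence string.
#' @param orf_seq The longest-ORF subsequence, or `""` when absent.
#' @return Named numeric vector of length 168; ORF-side names carry the
#'   `ORF_k_mer_` prefix.
#' @export
kmer_block <- function(seq, orf_seq = "") {
  tx <- unlist(lapply(1:3, function(k) kmer_freq(seq, k)))
  orf <- unlist(lapply(1:3, function(k) kmer_freq(orf_seq, k, prefix = "ORF_k_mer_")))
  c(tx, orf)
}

#' CTD distribution descriptors
#'
#' For each base, the relative positions (fraction of transcript length) at
#' which 0%, 25%, 50%, 75% and 100% of that base's occurrences have been
#' seen: the distribution component of the composition/transition/distribution
#' (CTD) descriptor family. A base that never occurs contributes five zeros.
#'
#' @param seq A normalized DNA sequence string.
#' @return Named numeric vector of length 20 (base-major order), names like
#'   `A_CTD_0`, `A_CTD_25`, ...
#' @export
ctd_distribution <- function(seq) {
  L <- nchar(seq)
  ch <- seq_chars(seq)
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  out <- stats::setNames(
    numeric(20),
    as.vector(t(outer(.dna_bases, c("0", "25", "50", "75", "100"),
                      function(b, q) paste0(b, "_CTD_", q))))
  )
  for (i in seq_along(.dna_bases)) {
    pos <- which(ch == .dna_bases[[i]])
    m <- length(pos)
    if (m == 0) next
    idx <- pmax(1L, ceiling(m * qs))   # 0% quantile -> first occurrence
    out[(i - 1) * 5 + seq_len(5)] <- pos[idx] / L
  }
  out
}

#' Entropy density profile
#'
#' Converts symbol counts into an entropy density profile: with
#' \eqn{p_i = c_i / \sum c}, each symbol contributes
#' \eqn{s_i = -p_i \log p_i / H} where \eqn{H} is the Shannon entropy of
#' \eqn{p} (natural log; the base cancels). The profile sums to 1 and
#' emphasizes symbols of intermediate frequency. A one-hot count vector has
#' zero entropy and is returned unchanged.
#'
#' @param counts Named nonnegative counts over an alphabet; at least one must
#'   be positive.
#' @return Named numeric vector over the same alphabet, summing to 1.
#' @export
edp_profile <- function(counts) {
  vals <- as.numeric(counts)
  if (any(vals < 0) || sum(vals) <= 0) {
    rlang::abort("edp_profile needs at least one positive count")
  }
  p <- vals / sum(vals)
  terms <- ifelse(p > 0, -p * log(p), 0)
  H <- sum(terms)
  out <- if (H == 0) p else terms / H
  names(out) <- names(counts)
  out
}

#' Codon-periodicity signal-to-noise ratio
#'
#' Builds the four binary base-indicator sequences, sums their power spectra
#' (squared modulus of the discrete Fourier transform), and returns the power
#' at the one-third frequency bin `k* = round(N/3)` divided by the mean power
#' over all non-DC bins. Coding sequences show a strong period-3 component
#' from codon structure, noncoding sequences do not. Defined as 0 for
#' sequences shorter than 6 nt and for the degenerate 0/0 case (e.g. a
#' homopolymer, whose non-DC power is zero).
#'
#' @param seq A normalized DNA sequence string.
#' @return A single nonnegative numeric value.
#' @examples
#' snr("ATGATGATGATG")  # 5.5
#' @export
snr <- function(seq) {
  N <- nchar(seq)
  if (N < 6) return(0)
  ch <- seq_chars(seq)
  power <- numeric(N)
  for (b in .dna_bases) {
    power <- power + Mod(stats::fft(as.numeric(ch == b)))^2
  }
  noise <- mean(power[2:N])
  if (noise == 0) return(0)
  k_star <- round(N / 3)
  power[k_star + 1] / noise
}

#' UTR coverage
#'
#' Lengths of the 5' and 3' untranslated regions flanking the longest ORF,
#' each divided by the transcript length; zeros when the transcript has no
#' ORF.
#'
#' @param profile An `lnc_orf_profile` from [orf_profile()].
#' @return Named numeric vector `UTR5_coverage`, `UTR3_coverage`.
#' @export
utr_coverage <- function(profile) {
  if (is.null(profile$longest_orf) || profile$L == 0) {
    return(c(UTR5_coverage = 0, UTR3_coverage = 0))
  }
  c(UTR5_coverage = (profile$utr5[2] - profile$utr5[1]) / profile$L,
    UTR3_coverage = (profile$utr3[2] - profile$utr3[1]) / profile$L)
}
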