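#' Translate an ORF subsequence to a peptide
#'
#' Standard genetic code translation of a DNA string. A trailing partial codon
#' is dropped, stop codons are skipped (so the terminal stop of a complete ORF
#' contributes nothing), and codons containing `N` are dropped.
#'
#' @param orf_seq A DNA string (typically a longest-ORF subsequence).
#' @return A peptide string over the 20 standard one-letter codes (possibly
#'   empty).
#' @examples
#' translate_orf("ATGAAATAA")  # "MK"
#' @export
translate_orf <- function(orf_seq) {
  if (nchar(orf_seq) < 3) return("")
  codons <- frame_codons(orf_seq, 0L)
  aas <- .codon_table[codons]          # NA for codons containing N
  aas <- aas[!is.na(aas) & aas != "*"]
  paste0(aas, collapse = "")
}

pep_residues <- function(pep) {
  if (nchar(pep) == 0) return(character(0))
  seq_chars(pep)
}

#' Peptide molecular weight
#'
#' Average-mass molecular weight (ExPASy convention): sum of average residue
#' masses plus one water. Empty peptide gives 0.
#'
#' @param pep A peptide string.
#' @return Mass in daltons.
#' @export
molecular_weight <- function(pep) {
  res <- pep_residues(pep)
  if (length(res) == 0) return(0)
  sum(.aa_mass[res]) + .water_mass
}

# Net charge of a peptide at a given pH (Henderson-Hasselbalch over the
# termini and the D, E, C, Y, H, K, R side chains, Bjellqvist pKa set).
peptide_charge <- function(res_counts, pH) {
  pos_ratio <- function(pka) 1 / (1 + 10^(pH - pka))
  neg_ratio <- function(pka) 1 / (1 + 10^(pka - pH))
  charge <- pos_ratio(.pka$n_term) - neg_ratio(.pka$c_term)
  for (aa in names(.pka$positive)) {
    charge <- charge + res_counts[[aa]] * pos_ratio(.pka$positive[[aa]])
  }
  for (aa in names(.pka$negative)) {
    charge <- charge - res_counts[[aa]] * neg_ratio(.pka$negative[[aa]])
  }
  charge
}

#' Theoretical isoelectric point
#'
#' The pH at which the peptide's net charge crosses zero, found by bisection
#' on \[0, 14\] to a tolerance of 1e-3 pH units. Charge is modeled with
#' Henderson-Hasselbalch terms for the two termini and the D, E, C, Y, H, K, R
#' side chains using the Bjellqvist pKa set. Empty peptide gives 0.
#'
#' @param pep A peptide string.
#' @return pH units.
#' @export
isoelectric_point <- function(pep) {
  res <- pep_residues(pep)
  if (length(res) == 0) return(0)
  counts <- table(factor(res, levels = .aa_order))
  res_counts <- stats::setNames(as.numeric(counts), .aa_order)
  lo <- 0; hi <- 14
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (peptide_charge(res_counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues; empty peptide gives 0.
#'
#' @param pep A peptide string.
#' @return Dimensionless mean hydropathy.
#' @export
gravy <- function(pep) {
  res <- pep_residues(pep)
  if (length(res) == 0) return(0)
  mean(.kd_hydropathy[res])
}

#' Guruprasad instability index
#'
#' `10/L` times the sum of dipeptide instability weight values (DIWV) over
#' consecutive residue pairs. Values above 40 suggest an unstable protein.
#' Peptides shorter than 2 residues give 0.
#'
#' @param pep A peptide string.
#' @return Dimensionless index.
#' @export
instability_index <- function(pep) {
  res <- pep_residues(pep)
  L <- length(res)
  if (L < 2) return(0)
  idx <- cbind(match(res[-L], .aa_order), match(res[-1], .aa_order))
  (10 / L) * sum(.diwv[idx])
}

# log10(pI / Mw) with a zero guard for degenerate peptides.
log_pi_mw <- function(pep) {
  mw <- molecular_weight(pep)
  pi <- isoelectric_point(pep)
  if (mw <= 0 || pi <= 0) return(0)
  log10(pi / mw)
}

#' Structure-related (peptide) feature block
#'
#' Translates the longest ORF and returns the six physicochemical features of
#' the predicted peptide: molecular weight, isoelectric point, log10(pI/Mw),
#' the pI/Mw frame score (population variance of log10(pI/Mw) over the
#' peptides of the per-frame longest ORFs, a missing frame contributing 0),
#' GRAVY, and the instability index. All six are 0 when the transcript has no
#' ORF.
#'
#' @param seq A normalized DNA sequence string.
#' @param profile An `lnc_orf_profile` from [orf_profile()].
#' @return Named numeric vector: `Mw`, `pI`, `pI_Mw`, `pI_Mw_frame_score`,
#'   `Gravy`, `Instability_index`.
#' @export
peptide_block <- function(seq, profile) {
  out <- c(Mw = 0, pI = 0, pI_Mw = 0, pI_Mw_frame_score = 0,
           Gravy = 0, Instability_index = 0)
  if (is.null(profile$longest_orf)) return(out)
  pep <- translate_orf(orf_subseq(seq, profile$longest_orf))
  frame_vals <- numeric(3)
  pf <- profile$per_frame_longest
  if (nrow(pf)) {
    for (i in seq_len(nrow(pf))) {
      f <- pf$frame[[i]]
      frame_vals[f + 1] <- log_pi_mw(translate_orf(orf_subseq(seq, pf[i, ])))
    }
  }
  c(Mw = molecular_weight(pep),
    pI = isoelectric_point(pep),
    pI_Mw = log_pi_mw(pep),
    pI_Mw_frame_score = pop_var(frame_vals),
    Gravy = gravy(pep),
    Instability_index = instability_index(pep))
}
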