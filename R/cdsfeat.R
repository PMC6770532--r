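#' Coding-sequence (CDS) feature block
#'
#' The most-likely CDS is taken to be the longest ORF. Returns the CDS length,
#' the CDS percentage (length over transcript length), and a deterministic
#' CDS score built from the same signals a dedicated CDS predictor rewards:
#' `length * (1 + max(0, hexamer_score))` plus 50 for a terminal stop codon
#' and 50 for an ATG start. The score is monotone in ORF length, completeness,
#' and coding-like hexamer composition. All three values are 0 when the
#' transcript has no ORF.
#'
#' An externally computed CDS call (e.g. from txCdsPredict output read with
#' [read_txcdspredict()]) can be supplied to override the built-in scoring.
#'
#' @param seq A normalized DNA sequence string.
#' @param profile An `lnc_orf_profile` from [orf_profile()].
#' @param table An `lnc_hexamer_table` used by the score.
#' @param call Optional one-row tibble with columns `start`, `end`, `score`
#'   (0-based half-open) overriding the built-in CDS call.
#' @return Named numeric vector `CDS_length`, `CDS_percentage`, `CDS_score`.
#' @export
cds_block <- function(seq, profile, table, call = NULL) {
  L <- nchar(seq)
  if (!is.null(call)) {
    len <- call$end - call$start
    return(c(CDS_length = len, CDS_percentage = if (L > 0) len / L else 0,
             CDS_score = call$score))
  }
  if (is.null(profile$longest_orf)) {
    return(c(CDS_length = 0, CDS_percentage = 0, CDS_score = 0))
  }
  orf <- profile$longest_orf
  len <- orf$length
  cds_seq <- orf_subseq(seq, orf)
  hs <- hexamer_score(cds_seq, table)
  score <- len * (1 + max(0, hs)) +
    50 * as.numeric(isTRUE(orf$has_stop)) +
    50 * as.numeric(startsWith(cds_seq, "ATG"))
  c(CDS_length = len, CDS_percentage = len / L, CDS_score = unname(score))
}

#' Read txCdsPredict output
#'
#' Reads the tab-separated output of the UCSC txCdsPredict program and
#' extracts one CDS call per transcript. By default the transcript name,
#' CDS start, CDS end and score are taken from columns 1, 2, 3 and 5 of the
#' file.
#'
#' @param path Path to a txCdsPredict `.cds` file (TSV, no header).
#' @param columns Integer positions of the name/start/end/score columns.
#' @return A tibble with columns `id`, `start`, `end`, `score`.
#' @export
read_txcdspredict <- function(path, columns = c(1L, 2L, 3L, 5L)) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (max(columns) > ncol(tab)) {
    rlang::abort("txCdsPredict file has fewer columns than expected")
  }
  tibble::tibble(id = as.character(tab[[columns[1]]]),
                 start = as.integer(tab[[columns[2]]]),
                 end = as.integer(tab[[columns[3]]]),
                 score = as.numeric(tab[[columns[4]]]))
}
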