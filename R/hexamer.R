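# In-frame hexamers of a sequence: windows of width 6 advancing by 3 nt from
# position 0; windows containing N are skipped.
inframe_hexamers <- function(seq) {
  L <- nchar(seq)
  if (L < 6) return(character(0))
  starts <- seq.int(1L, L - 5L, by = 3L)
  hx <- substring(seq, starts, starts + 5L)
  hx[!grepl("N", hx, fixed = TRUE)]
}

#' Train an in-frame hexamer frequency table
#'
#' Builds the coding and noncoding hexamer background tables used by the
#' hexamer score. Hexamers are counted in frame (step 3, starting at position
#' 0): for coding training sequences over their longest ORF subsequence (the
#' raw sequence is used when a training sequence contains no ORF), for
#' noncoding sequences over the raw sequence. A pseudocount is added to every
#' one of the 4096 cells before normalization, so every hexamer has positive
#' probability.
#'
#' @param coding,noncoding Character vectors of normalized DNA sequences (or
#'   tibbles with a `seq` column).
#' @param pseudocount Positive smoothing constant added to each cell.
#' @return An object of class `lnc_hexamer_table`: a list with `coding_freq`
#'   and `noncoding_freq` (named probability vectors over all 4096 hexamers),
#'   `pseudocount`, `n_coding`, `n_noncoding`.
#' @export
train_hexamer_table <- function(coding, noncoding, pseudocount = 1) {
  get_seqs <- function(x) if (is.data.frame(x)) x$seq else x
  coding <- get_seqs(coding); noncoding <- get_seqs(noncoding)
  if (length(coding) == 0 || length(noncoding) == 0) {
    rlang::abort("both training collections must be non-empty")
  }
  stopifnot(pseudocount > 0)
  hexamers <- all_kmers(6)
  count_set <- function(seqs, use_orf) {
    counts <- stats::setNames(numeric(4096), hexamers)
    for (s in seqs) {
      if (use_orf) {
        prof <- orf_profile(s)
        if (!is.null(prof$longest_orf)) s <- orf_subseq(s, prof$longest_orf)
      }
      hx <- inframe_hexamers(s)
      if (length(hx)) {
        tab <- table(hx)
        counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
      }
    }
    counts
  }
  cod <- count_set(coding, use_orf = TRUE) + pseudocount
  non <- count_set(noncoding, use_orf = FALSE) + pseudocount
  structure(
    list(coding_freq = cod / sum(cod), noncoding_freq = non / sum(non),
         pseudocount = pseudocount,
         n_coding = length(coding), n_noncoding = length(noncoding)),
    class = "lnc_hexamer_table"
  )
}

#' Neutral hexamer table
#'
#' A table whose coding and noncoding backgrounds are both uniform, so every
#' hexamer score is exactly 0. Useful as a placeholder and in tests.
#'
#' @return An `lnc_hexamer_table`.
#' @export
neutral_hexamer_table <- function() {
  hexamers <- all_kmers(6)
  u <- stats::setNames(rep(1 / 4096, 4096), hexamers)
  structure(list(coding_freq = u, noncoding_freq = u, pseudocount = 1,
                 n_coding = 0L, n_noncoding = 0L),
            class = "lnc_hexamer_table")
}

#' Hexamer usage score
#'
#' Mean log-ratio of coding to noncoding background frequency over the
#' in-frame hexamers of an ORF subsequence. Positive values indicate
#' coding-like hexamer usage, negative values noncoding-like usage; sequences
#' with no complete in-frame hexamer score 0.
#'
#' @param orf_seq The longest-ORF subsequence (or any in-frame DNA string).
#' @param table An `lnc_hexamer_table`.
#' @return A single numeric score.
#' @export
hexamer_score <- function(orf_seq, table) {
  stopifnot(inherits(table, "lnc_hexamer_table"))
  hx <- inframe_hexamers(orf_seq)
  if (length(hx) == 0) return(0)
  mean(log(table$coding_freq[hx] / table$noncoding_freq[hx]))
}

#' Write / read a hexamer table as TSV
#'
#' The table is serialized as a three-column TSV (`hexamer`, `coding_freq`,
#' `noncoding_freq`) preceded by `#`-comment header lines recording the
#' training-set sizes and the pseudocount.
#'
#' @param table An `lnc_hexamer_table`.
#' @param path File path.
#' @return `path` (write) or an `lnc_hexamer_table` (read).
#' @export
write_hexamer_table <- function(table, path) {
  stopifnot(inherits(table, "lnc_hexamer_table"))
  header <- c(
    sprintf("# n_coding=%d", table$n_coding),
    sprintf("# n_noncoding=%d", table$n_noncoding),
    sprintf("# pseudocount=%.10g", table$pseudocount)
  )
  writeLines(header, path)
  tab <- tibble::tibble(hexamer = names(table$coding_freq),
                        coding_freq = unname(table$coding_freq),
                        noncoding_freq = unname(table$noncoding_freq))
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_hexamer_table
#' @export
read_hexamer_table <- function(path) {
  header <- readLines(path, n = 10)
  header <- header[startsWith(header, "#")]
  meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), header, value = TRUE)
    if (length(hit)) as.numeric(sub(".*=", "", hit[[1]])) else default
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("hexamer", "coding_freq", "noncoding_freq") %in% names(tab)))
  if (nrow(tab) != 4096) rlang::abort("hexamer table must have 4096 rows")
  structure(
    list(coding_freq = stats::setNames(tab$coding_freq, tab$hexamer),
         noncoding_freq = stats::setNames(tab$noncoding_freq, tab$hexamer),
         pseudocount = meta("pseudocount", 1),
         n_coding = as.integer(meta("n_coding", 0)),
         n_noncoding = as.integer(meta("n_noncoding", 0))),
    class = "lnc_hexamer_table"
  )
}
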