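#' Normalize a raw nucleotide sequence
#'
#' Uppercases the sequence, folds RNA to DNA (`U` to `T`), and replaces any
#' remaining character outside `{A,C,G,T}` with the ambiguity sentinel `N`.
#' Sequences whose ambiguous fraction exceeds 10% after normalization are
#' rejected; downstream k-mer windows containing `N` are skipped, so a small
#' amount of ambiguity leaves every feature well defined.
#'
#' @param raw A single non-empty character string.
#' @return The normalized sequence (characters in `{A,C,G,T,N}`).
#' @examples
#' normalize_sequence("augc")
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1)
  if (is.na(raw) || nchar(raw) == 0) {
    rlang::abort("empty sequence")
  }
  seq <- chartr("U", "T", toupper(raw))
  seq <- gsub("[^ACGT]", "N", seq)
  n_ambig <- stringr::str_count(seq, stringr::fixed("N"))
  if (n_ambig / nchar(seq) > 0.10) {
    rlang::abort("too ambiguous")
  }
  seq
}

#' Read transcripts from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a tibble of transcripts,
#' applying [normalize_sequence()] to every record. Records that fail
#' normalization (empty body, or more than 10% ambiguous bases) are dropped
#' and logged; input order is preserved for the records that survive.
#'
#' @param path Path to a FASTA file.
#' @param reject_log Optional path; when given, rejected record ids and
#'   reasons are written there as a two-column TSV.
#' @return A tibble with columns `id` (first whitespace-delimited header
#'   token), `seq`, and `length`, with the rejection log attached as the
#'   `"rejections"` attribute (a tibble with columns `id`, `reason`).
#' @export
read_fasta <- function(path, reject_log = NULL) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) rlang::abort(sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(set) == 0) {
    rlang::abort(sprintf("no FASTA records found in '%s'", path))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  raw <- as.character(set)
  rejects <- list()
  rows <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    norm <- tryCatch(normalize_sequence(raw[[i]]), error = function(e) e)
    if (inherits(norm, "error")) {
      rejects[[length(rejects) + 1]] <-
        tibble::tibble(id = ids[[i]], reason = conditionMessage(norm))
    } else {
      rows[[i]] <- tibble::tibble(id = ids[[i]], seq = norm)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble::tibble(id = character(), seq = character())
  out <- dplyr::mutate(out, length = nchar(.data$seq))
  rejections <- if (length(rejects)) dplyr::bind_rows(rejects) else
    tibble::tibble(id = character(), reason = character())
  if (!is.null(reject_log)) {
    readr::write_tsv(rejections, reject_log)
  }
  attr(out, "rejections") <- rejections
  out
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts A tibble with columns `id` and `seq`.
#' @param path Output file path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(transcripts)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(transcripts))) {
    writeLines(paste0(">", transcripts$id[[i]]), con)
    s <- transcripts$seq[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Filter transcripts by length
#'
#' Keeps transcripts strictly longer than `min_len` and strictly shorter than
#' `max_len`. The defaults reproduce the usual lncRNA working range: longer
#' than 200 nt and under 3000 nt, with both bounds excluded.
#'
#' @param transcripts A tibble with a `length` column (as from [read_fasta()]).
#' @param min_len,max_len Exclusive length bounds in nucleotides.
#' @return The filtered tibble (order and duplicates preserved).
#' @export
filter_by_length <- function(transcripts, min_len = 200, max_len = 3000) {
  stopifnot(min_len < max_len)
  dplyr::filter(transcripts, .data$length > min_len, .data$length < max_len)
}
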