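#' Enumerate open reading frames on the forward strand
#'
#' Every `ATG` in every forward frame opens a candidate ORF that runs to the
#' first in-frame stop codon (`TAA`/`TAG`/`TGA`); the stop codon is included
#' in the ORF, so a complete start-to-stop ORF of a full-CDS transcript covers
#' the whole sequence. When no in-frame stop follows, the ORF runs to the last
#' complete codon and is flagged `has_stop = FALSE`. Nested starts each yield
#' their own candidate. Transcripts are treated as mRNA-sense, so only the
#' forward strand is scanned.
#'
#' @param seq A normalized DNA sequence string.
#' @return A tibble with columns `frame` (0/1/2), `start` (0-based inclusive),
#'   `end` (0-based exclusive), `length` (nt, stop included), `has_stop`.
#' @examples
#' find_orfs("ATGAAATAA")
#' @export
find_orfs <- function(seq) {
  L <- nchar(seq)
  empty <- tibble::tibble(frame = integer(), start = integer(), end = integer(),
                          length = integer(), has_stop = logical())
  if (L < 3) return(empty)
  ch <- seq_chars(seq)
  i <- seq_len(L - 2L)
  is_atg <- ch[i] == "A" & ch[i + 1L] == "T" & ch[i + 2L] == "G"
  is_stop <- ch[i] == "T" &
    ((ch[i + 1L] == "A" & (ch[i + 2L] == "A" | ch[i + 2L] == "G")) |
       (ch[i + 1L] == "G" & ch[i + 2L] == "A"))
  atg_pos <- which(is_atg)        # 1-based codon start positions
  if (length(atg_pos) == 0) return(empty)
  stop_pos <- which(is_stop)
  rows <- vector("list", length(atg_pos))
  for (j in seq_along(atg_pos)) {
    a <- atg_pos[[j]]
    f <- (a - 1L) %% 3L
    frame_stops <- stop_pos[stop_pos >= a & (stop_pos - a) %% 3L == 0L]
    if (length(frame_stops)) {
      s <- frame_stops[[1]]
      end0 <- s + 2L                       # 0-based exclusive == 1-based inclusive end
      has_stop <- TRUE
    } else {
      n_codons <- (L - a + 1L) %/% 3L
      end0 <- (a - 1L) + 3L * n_codons
      has_stop <- FALSE
    }
    rows[[j]] <- list(frame = f, start = a - 1L, end = end0,
                      length = end0 - (a - 1L), has_stop = has_stop)
  }
  dplyr::bind_rows(rows)
}

#' Summarize the ORF structure of a transcript
#'
#' Identifies the first and the longest ORF, the longest ORF length within
#' each of the three forward frames, and the 5'/3' untranslated regions
#' flanking the longest ORF. Ties are broken deterministically: the first ORF
#' is the one with the smallest start (preferring a stop-terminated, then a
#' longer ORF); the longest ORF is the maximum-length one (preferring the
#' smallest start, then a stop-terminated ORF).
#'
#' @param seq A normalized DNA sequence string.
#' @return An object of class `lnc_orf_profile`: a list with elements
#'   `orfs` (tibble from [find_orfs()]), `first_orf`, `longest_orf` (one-row
#'   tibbles or `NULL`), `per_frame_longest_len` (3 integers),
#'   `per_frame_longest` (tibble of the per-frame longest ORFs),
#'   `utr5`/`utr3` (0-based half-open intervals, `c(lo, hi)`), and `L`.
#' @export
orf_profile <- function(seq) {
  L <- nchar(seq)
  orfs <- find_orfs(seq)
  per_frame <- integer(3)
  per_frame_rows <- list()
  first_orf <- NULL
  longest_orf <- NULL
  if (nrow(orfs) > 0) {
    o_first <- dplyr::arrange(orfs, .data$start, dplyr::desc(.data$has_stop),
                              dplyr::desc(.data$length))
    first_orf <- o_first[1, ]
    o_long <- dplyr::arrange(orfs, dplyr::desc(.data$length), .data$start,
                             dplyr::desc(.data$has_stop))
    longest_orf <- o_long[1, ]
    for (f in 0:2) {
      sub <- o_long[o_long$frame == f, ]
      if (nrow(sub)) {
        per_frame[f + 1L] <- sub$length[[1]]
        per_frame_rows[[length(per_frame_rows) + 1]] <- sub[1, ]
      }
    }
  }
  utr5 <- if (is.null(longest_orf)) c(0L, 0L) else c(0L, longest_orf$start)
  utr3 <- if (is.null(longest_orf)) c(0L, 0L) else c(longest_orf$end, L)
  structure(
    list(orfs = orfs, first_orf = first_orf, longest_orf = longest_orf,
         per_frame_longest_len = per_frame,
         per_frame_longest = dplyr::bind_rows(per_frame_rows),
         utr5 = utr5, utr3 = utr3, L = L),
    class = "lnc_orf_profile"
  )
}

# Subsequence of `seq` covered by a one-row ORF tibble (or NULL -> "").
orf_subseq <- function(seq, orf) {
  if (is.null(orf) || nrow(orf) == 0) return("")
  substr(seq, orf$start + 1L, orf$end)
}

#' ORF scalar feature block
#'
#' The six ORF-level scalars: first and longest ORF length, their coverages
#' (length divided by transcript length), ORF integrity (+1 when the longest
#' ORF both starts with ATG and ends at a stop codon, -1 otherwise), and the
#' ORF frame score, the population variance of the longest ORF length per
#' forward frame.
#'
#' @param profile An `lnc_orf_profile` from [orf_profile()].
#' @return A named numeric vector of length 6.
#' @export
orf_scalar_block <- function(profile) {
  L <- profile$L
  if (is.null(profile$longest_orf)) {
    return(c(first_orf_length = 0, longest_orf_length = 0,
             longest_orf_coverage = 0, first_orf_coverage = 0,
             orf_integrity = -1, orf_frame_score = 0))
  }
  first_len <- profile$first_orf$length
  longest_len <- profile$longest_orf$length
  c(first_orf_length = first_len,
    longest_orf_length = longest_len,
    longest_orf_coverage = longest_len / L,
    first_orf_coverage = first_len / L,
    orf_integrity = if (isTRUE(profile$longest_orf$has_stop)) 1 else -1,
    orf_frame_score = pop_var(profile$per_frame_longest_len))
}

#' Write ORF coordinates as a BED-like TSV
#'
#' @param profile An `lnc_orf_profile`.
#' @param id Transcript identifier used in the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_bed <- function(profile, id, path) {
  tab <- dplyr::mutate(profile$orfs, id = id, .before = 1)
  readr::write_tsv(tab, path)
  invisible(path)
}
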