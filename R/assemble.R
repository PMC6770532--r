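schema_env <- new.env(parent = emptyenv())

#' The canonical 260-feature schema
#'
#' The fixed, ordered naming of the 260 global sequence features, grouped into
#' six categories: codon-related (9), ORF-related (22), GC-related (7),
#' CDS-related (3), transcript-related (213) and structure-related (6).
#' The order is stable across runs and machines; every feature table and model
#' in the package is aligned to it.
#'
#' @return A tibble with columns `name` and `category` (260 rows).
#' @export
feature_schema <- function() {
  if (!is.null(schema_env$schema)) return(schema_env$schema)
  codon <- c("stop_codon_count", "stop_codon_freq", "stop_codon_frame_score",
             "stop_codon_freq_frame_score",
             paste0(.dna_bases, "_pos_fickett"), "fickett_score")
  orf <- c("first_orf_length", "longest_orf_length", "longest_orf_coverage",
           "first_orf_coverage", "orf_integrity", "orf_frame_score",
           paste0("EDP_ORF_k_mer_", all_kmers(2)))
  gc <- c("GC_content", "GC1", "GC2", "GC3", "GC_frame_score", "UTR5_GC", "UTR3_GC")
  cds <- c("CDS_length", "CDS_percentage", "CDS_score")
  transcript <- c(
    "transcript_length",
    unlist(lapply(1:3, all_kmers)),
    paste0("ORF_k_mer_", unlist(lapply(1:3, all_kmers))),
    as.vector(t(outer(.dna_bases, c("0", "25", "50", "75", "100"),
                      function(b, q) paste0(b, "_CTD_", q)))),
    "hexamer_score", "SNR", "UTR5_coverage", "UTR3_coverage",
    paste0("EDP_fea_", .aa_order)
  )
  structure_feats <- c("Mw", "pI", "pI_Mw", "pI_Mw_frame_score",
                       "Gravy", "Instability_index")
  schema <- tibble::tibble(
    name = c(codon, orf, gc, cds, transcript, structure_feats),
    category = rep(
      c("codon", "ORF", "GC", "CDS", "transcript", "structure"),
      times = c(length(codon), length(orf), length(gc), length(cds),
                length(transcript), length(structure_feats))
    )
  )
  stopifnot(nrow(schema) == 260, !anyDuplicated(schema$name))
  schema_env$schema <- schema
  schema
}

# Hash identifying the schema; stored in trained models and verified at
# prediction and load time.
schema_hash <- function(schema = feature_schema()) {
  rlang::hash(schema$name)
}

# The full 260-value feature vector of one transcript (named numeric).
extract_one <- function(seq, table) {
  profile <- orf_profile(seq)
  orf_seq <- orf_subseq(seq, profile$longest_orf)
  L <- nchar(seq)

  edp_orf <- stats::setNames(numeric(16), paste0("EDP_ORF_k_mer_", all_kmers(2)))
  if (nchar(orf_seq) >= 2) {
    dinuc <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(orf_seq), 2)
    if (sum(dinuc) > 0) edp_orf[] <- edp_profile(as.numeric(dinuc[all_kmers(2)]))
  }

  pep_tx <- translate_orf(seq)   # frame-0 translation of the whole transcript
  edp_tx <- stats::setNames(numeric(20), paste0("EDP_fea_", .aa_order))
  if (nchar(pep_tx) > 0) {
    aa_counts <- table(factor(seq_chars(pep_tx), levels = .aa_order))
    edp_tx[] <- edp_profile(as.numeric(aa_counts))
  }

  c(stop_codon_block(seq),
    position_frequency_block(seq),
    fickett_score = fickett_score(seq),
    orf_scalar_block(profile),
    edp_orf,
    gc_block(seq, profile),
    cds_block(seq, profile, table),
    transcript_length = L,
    kmer_block(seq, orf_seq),
    ctd_distribution(seq),
    hexamer_score = hexamer_score(orf_seq, table),
    SNR = snr(seq),
    utr_coverage(profile),
    edp_tx,
    peptide_block(seq, profile))
}

#' Extract the 260-dimension feature table
#'
#' Computes the full global-sequence feature vector for each transcript:
#' stop-codon statistics, nucleotide position frequencies and Fickett score;
#' ORF scalars and ORF dinucleotide entropy density; GC composition; CDS
#' features; transcript length, k-mers, CTD distribution, hexamer score, SNR,
#' UTR coverage and amino-acid entropy density; and the six peptide
#' (structure) features. Extraction is deterministic and never produces
#' `NA`/`NaN`/`Inf`.
#'
#' @param transcripts A tibble with columns `id` and `seq` (optionally
#'   `label`), as returned by [read_fasta()] or [synth_transcripts()]; or a
#'   path to a FASTA file; or a named character vector of sequences.
#' @param table An `lnc_hexamer_table` (see [train_hexamer_table()]); the
#'   hexamer score and CDS score are computed against it.
#' @return A tibble with `id`, optional `label`, and the 260 feature columns
#'   in schema order.
#' @export
extract_features <- function(transcripts, table = neutral_hexamer_table()) {
  stopifnot(inherits(table, "lnc_hexamer_table"))
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts)
  }
  if (is.character(transcripts)) {
    ids <- names(transcripts)
    if (is.null(ids)) ids <- paste0("seq_", seq_along(transcripts))
    transcripts <- tibble::tibble(id = ids, seq = unname(transcripts))
  }
  stopifnot(all(c("id", "seq") %in% names(transcripts)))
  schema <- feature_schema()
  mat <- matrix(0, nrow = nrow(transcripts), ncol = 260,
                dimnames = list(NULL, schema$name))
  for (i in seq_len(nrow(transcripts))) {
    v <- extract_one(transcripts$seq[[i]], table)
    stopifnot(identical(names(v), schema$name))
    mat[i, ] <- v
  }
  stopifnot(all(is.finite(mat)))
  out <- tibble::tibble(id = transcripts$id)
  if ("label" %in% names(transcripts)) out$label <- transcripts$label
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

#' Write / read a feature table as TSV
#'
#' The on-disk format is a UTF-8 TSV whose header is `id`, `label`, then the
#' 260 schema feature names; `label` may be empty. Reading verifies the header
#' against the schema and fails naming the first offending column. Numeric
#' values round-trip to at least 12 significant digits.
#'
#' @param features A feature tibble from [extract_features()].
#' @param path File path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_table <- function(features, path) {
  schema <- feature_schema()
  if (!"label" %in% names(features)) {
    features <- dplyr::mutate(features, label = NA_character_, .after = "id")
  }
  features <- features[, c("id", "label", schema$name)]
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           label = readr::col_character(),
                           .default = readr::col_double()
                         ))
  schema <- feature_schema()
  expected <- c("id", "label", schema$name)
  if (!identical(names(tab), expected)) {
    bad <- c(setdiff(names(tab), expected), setdiff(expected, names(tab)))
    rlang::abort(sprintf(
      "feature table does not match the 260-feature schema (offending column: %s)",
      bad[1]
    ))
  }
  tab
}
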