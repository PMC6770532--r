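#' Synthetic-transcript generator configuration
#'
#' Study conditions for the synthetic datasets used to calibrate and test the
#' classifier. Coding-like transcripts carry a long (at least 60% of the
#' transcript) codon-biased ORF flanked by background UTRs; noncoding-like
#' transcripts are drawn from a low-order Markov background fitted to a target
#' GC content, with no enforced codon structure.
#'
#' `codon_bias_strength` controls how sharply the ORF codon distribution is
#' concentrated (via a Dirichlet draw over the 61 non-stop codons, one draw
#' per dataset seed). At strength 0 the coding construction is disabled
#' entirely and "coding" sequences are drawn from the same Markov background
#' as the noncoding set: the null model in which the two classes are
#' statistically indistinguishable.
#'
#' @param n_coding,n_noncoding Number of transcripts per class.
#' @param len_min,len_max Transcript length range (nt), uniform.
#' @param codon_bias_strength Codon-bias sharpness in \[0, 1\]; 0 = null
#'   model.
#' @param gc_target Target GC content of the Markov background, in (0, 1).
#' @param markov_order Order of the background Markov chain.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_coding = 500, n_noncoding = 500,
                         len_min = 200, len_max = 3000,
                         codon_bias_strength = 0.75, gc_target = 0.5,
                         markov_order = 2, seed = 1) {
  stopifnot(n_coding >= 0, n_noncoding >= 0, len_min < len_max,
            codon_bias_strength >= 0, codon_bias_strength <= 1,
            gc_target > 0, gc_target < 1, markov_order >= 1)
  structure(list(n_coding = n_coding, n_noncoding = n_noncoding,
                 len_min = len_min, len_max = len_max,
                 codon_bias_strength = codon_bias_strength,
                 gc_target = gc_target, markov_order = markov_order,
                 seed = seed),
            class = "synth_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Per-dataset background parameters: a Markov transition table over contexts
# of `markov_order` bases whose rows are Dirichlet draws centred on the base
# distribution implied by gc_target, plus the dataset's codon-usage weights.
synth_params <- function(cfg) {
  base_p <- c(A = (1 - cfg$gc_target) / 2, C = cfg$gc_target / 2,
              G = cfg$gc_target / 2, T = (1 - cfg$gc_target) / 2)
  n_ctx <- 4L^cfg$markov_order
  # concentration 60 keeps the realized GC within a few percent of target
  trans <- t(vapply(seq_len(n_ctx), function(i) rdirichlet1(60 * base_p),
                    numeric(4)))
  colnames(trans) <- .dna_bases
  non_stop <- setdiff(names(.codon_table), .stop_codons)
  s <- cfg$codon_bias_strength
  conc <- (1 - s) * 20 + s * 0.15
  codon_w <- stats::setNames(rdirichlet1(rep(conc, length(non_stop))), non_stop)
  list(base_p = base_p, trans = trans, trans_cum = t(apply(trans, 1, cumsum)),
       codon_w = codon_w, non_stop = non_stop)
}

# One background Markov sequence of length L (character string).
markov_seq <- function(L, params, order) {
  out <- integer(L)
  base_cum <- cumsum(params$base_p)
  n_init <- min(order, L)
  out[seq_len(n_init)] <- findInterval(stats::runif(n_init),
                                       base_cum, left.open = TRUE) + 1L
  if (L > order) {
    u <- stats::runif(L - order)
    pow <- 4L^(seq_len(order) - 1L)
    cum <- params$trans_cum
    ctx <- sum((out[seq_len(order)] - 1L) * rev(pow)) + 1L
    for (i in (order + 1L):L) {
      b <- findInterval(u[i - order], cum[ctx, ], left.open = TRUE) + 1L
      out[i] <- b
      # slide the context window: drop the oldest base, append the new one
      ctx <- ((ctx - 1L) %% (4L^(order - 1L))) * 4L + (b - 1L) + 1L
    }
  }
  paste(.dna_bases[out], collapse = "")
}

# One coding-like sequence of length L: background UTR5 + ATG + biased
# non-stop codons + stop + background UTR3, with the ORF covering >= min_cov.
coding_seq <- function(L, params, order, min_cov = 0.6) {
  u <- stats::runif(1, min_cov, 0.9)
  n_codons <- min(ceiling(u * L / 3), L %/% 3L)   # >= ceil(min_cov*L/3)
  orf_len <- 3L * n_codons
  n_internal <- n_codons - 2L
  codons <- sample(params$non_stop, n_internal, replace = TRUE,
                   prob = params$codon_w)
  orf <- paste0("ATG", paste(codons, collapse = ""),
                sample(.stop_codons, 1))
  rest <- L - orf_len
  utr5_len <- if (rest > 0) sample.int(rest + 1L, 1) - 1L else 0L
  utr3_len <- rest - utr5_len
  paste0(if (utr5_len > 0) markov_seq(utr5_len, params, order) else "",
         orf,
         if (utr3_len > 0) markov_seq(utr3_len, params, order) else "")
}

#' Generate coding-like synthetic transcripts
#'
#' Each transcript is a background 5' UTR, then an ATG-initiated ORF of
#' codon-biased non-stop codons closed by a stop codon, then a background
#' 3' UTR. The ORF covers at least 60% of the transcript, and rejection
#' sampling guarantees that it is exactly the longest ORF of the sequence
#' (so every coding transcript has ORF integrity +1 and longest-ORF coverage
#' of at least 0.6). With `codon_bias_strength = 0` the null model is used
#' instead: plain background sequences labelled coding.
#'
#' @param cfg A [synth_config()].
#' @param params Internal background parameters; regenerated from `cfg$seed`
#'   when not supplied.
#' @return A tibble with columns `id`, `seq`, `length`, `label`.
#' @export
generate_coding <- function(cfg, params = NULL) {
  with_seed(cfg$seed * 2L + 1L, {
    if (is.null(params)) params <- synth_params(cfg)
    null_model <- cfg$codon_bias_strength == 0
    seqs <- character(cfg$n_coding)
    lens <- sample(cfg$len_min:cfg$len_max, cfg$n_coding, replace = TRUE)
    for (i in seq_len(cfg$n_coding)) {
      if (null_model) {
        seqs[i] <- markov_seq(lens[i], params, cfg$markov_order)
      } else {
        for (try in 1:100) {
          s <- coding_seq(lens[i], params, cfg$markov_order)
          prof <- orf_profile(s)
          ok <- !is.null(prof$longest_orf) &&
            isTRUE(prof$longest_orf$has_stop) &&
            prof$longest_orf$length / lens[i] >= 0.6
          if (ok) break
        }
        if (!ok) rlang::abort("could not construct a valid coding transcript")
        seqs[i] <- s
      }
    }
    tibble::tibble(id = sprintf("cod_%05d", seq_len(cfg$n_coding)),
                   seq = seqs, length = nchar(seqs), label = "coding")
  })
}

#' Generate noncoding-like synthetic transcripts
#'
#' Sequences drawn from the dataset's background Markov chain (order
#' `markov_order`, fitted to `gc_target`), with no enforced codon structure.
#'
#' @inheritParams generate_coding
#' @return A tibble with columns `id`, `seq`, `length`, `label`.
#' @export
generate_noncoding <- function(cfg, params = NULL) {
  with_seed(cfg$seed * 2L, {
    if (is.null(params)) params <- synth_params(cfg)
    lens <- sample(cfg$len_min:cfg$len_max, cfg$n_noncoding, replace = TRUE)
    seqs <- vapply(lens, markov_seq, character(1),
                   params = params, order = cfg$markov_order)
    tibble::tibble(id = sprintf("nc_%05d", seq_len(cfg$n_noncoding)),
                   seq = seqs, length = nchar(seqs), label = "lncRNA")
  })
}

#' Generate a labelled synthetic dataset
#'
#' Draws the per-dataset background and codon-usage parameters from the seed,
#' then generates both classes. The result is a deterministic function of the
#' configuration.
#'
#' @param cfg A [synth_config()].
#' @return A tibble with columns `id`, `seq`, `length`, `label` (coding rows
#'   first).
#' @export
synth_transcripts <- function(cfg = synth_config()) {
  params <- with_seed(cfg$seed, synth_params(cfg))
  dplyr::bind_rows(generate_coding(cfg, params),
                   generate_noncoding(cfg, params))
}

#' Write a synthetic dataset to disk
#'
#' Writes `coding.fa`, `noncoding.fa`, `labels.tsv` and `metadata.json`
#' (configuration and seed) into a directory.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return The combined transcript tibble, invisibly.
#' @export
generate_dataset <- function(cfg = synth_config(), dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tx <- synth_transcripts(cfg)
  write_fasta(dplyr::filter(tx, .data$label == "coding"),
              file.path(dir, "coding.fa"))
  write_fasta(dplyr::filter(tx, .data$label == "lncRNA"),
              file.path(dir, "noncoding.fa"))
  readr::write_tsv(dplyr::select(tx, "id", "label", "length"),
                   file.path(dir, "labels.tsv"))
  jsonlite::write_json(unclass(cfg), file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tx)
}
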