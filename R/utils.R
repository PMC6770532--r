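# Internal helpers shared across modules.

# Population variance (divide by n, not n-1): every "frame score" feature is
# the spread of a statistic across exactly the three forward reading frames,
# a full population rather than a sample.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

# Complete in-frame codons of `seq` starting at 0-based offset `frame`;
# trailing partial codons are dropped.
frame_codons <- function(seq, frame = 0L) {
  L <- nchar(seq)
  n_codons <- (L - frame) %/% 3L
  if (n_codons <= 0L) return(character(0))
  starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
  substring(seq, starts, starts + 2L)
}

# Normalize labels to a factor with levels c("coding", "lncRNA");
# lncRNA is the positive class throughout the package.
as_label_factor <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.numeric(y)) y <- ifelse(y == 1, "lncRNA", "coding")
  if (!all(y %in% c("coding", "lncRNA"))) {
    rlang::abort("labels must be 'coding'/'lncRNA' (or 0/1 with 1 = lncRNA)")
  }
  factor(y, levels = c("coding", "lncRNA"))
}

# Extract the numeric feature matrix (schema order) from a feature tibble,
# a plain matrix, or a data.frame; validates column names against the schema.
feature_matrix <- function(x, schema_names = feature_schema()$name) {
  if (is.matrix(x)) {
    m <- x
  } else {
    stopifnot(is.data.frame(x))
    keep <- setdiff(names(x), c("id", "label"))
    m <- as.matrix(x[, keep, drop = FALSE])
  }
  if (!is.null(schema_names)) {
    if (!identical(colnames(m), schema_names)) {
      bad <- which(!(colnames(m) %in% schema_names))
      rlang::abort(sprintf(
        "feature columns do not match the 260-feature schema (first offending column: %s)",
        if (length(bad)) colnames(m)[bad[1]] else "<missing columns>"
      ))
    }
  }
  storage.mode(m) <- "double"
  m
}
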