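# Internal helpers shared across modules.

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
# All generator and NMF randomness flows through this so that a top-level
# seed gives byte-identical results regardless of the surrounding session.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage label, deterministically
# and within 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  as.integer(x)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Coerce a gene x feature tibble (id column first) to a numeric matrix with
# rownames; pass matrices through unchanged.
as_feature_matrix <- function(x, id_col = NULL) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (is.null(id_col)) {
    id_col <- names(x)[1]
  }
  m <- as.matrix(dplyr::select(x, -dplyr::all_of(id_col)))
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x[[id_col]])
  m
}
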