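# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed for a named stream hanging off one global seed.
# Lets each generated table draw from its own reproducible stream.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Column-standardize a numeric matrix; constant columns get sd 1 (stay 0).
standardize_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  list(
    x = sweep(sweep(x, 2, mu, "-"), 2, sdev, "/"),
    mean = mu, sd = sdev
  )
}

# Extract a participants x features numeric matrix from a tibble that carries
# a participant_id column; keeps ids as rownames.
tbl_to_matrix <- function(tbl, id_col = "participant_id") {
  stopifnot(id_col %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- as.character(tbl[[id_col]])
  storage.mode(m) <- "double"
  m
}

matrix_to_tbl <- function(m, id = rownames(m), id_col = "participant_id") {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  out <- tibble::add_column(out, !!id_col := id, .before = 1)
  out
}

# Fix the sign of each column of a loading matrix so its largest-|value|
# entry is positive. Deterministic tie-break: first index wins.
fix_column_signs <- function(v) {
  if (ncol(v) == 0) return(v)
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

pattern_labels <- function(k) sprintf("pattern_%02d", seq_len(k))
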