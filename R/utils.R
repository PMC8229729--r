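# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Locale-independent lexicographic sort, so aligned cell order (and therefore
# every seeded split) is identical across platforms.
sort_ids <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kesvr <- function(...) stop(..., call. = FALSE)

# Seeded 75/25-style index split. Returns sorted indices so downstream code
# never depends on sample() ordering.
split_indices <- function(n, fraction, seed) {
  size <- round(fraction * n)
  size <- min(max(size, 2L), n - 1L)
  idx <- with_seed(seed, sample.int(n, size))
  list(train = sort(idx), test = setdiff(seq_len(n), sort(idx)))
}

# Rank vector normalised to zero mean / unit L2 norm; NULL for constant input.
# Spearman correlation of two vectors is the dot product of their normalised
# rank vectors (average ranks for ties).
rank_normalize <- function(v) {
  r <- rank(v)
  r <- r - mean(r)
  s <- sqrt(sum(r^2))
  if (s == 0) return(NULL)
  r / s
}

# Rows = cells, columns = target genes. Constant-profile rows become all-zero
# rows (they contribute 0 to any Spearman average, by design).
rank_normalize_rows <- function(m) {
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    rn <- rank_normalize(m[i, ])
    if (!is.null(rn)) out[i, ] <- rn
  }
  out
}
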