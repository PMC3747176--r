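# internal helpers shared across the pipeline

# Deterministic substream seed from a base seed and one or two indices.
# Kept below 2^31 - 1 so set.seed() always receives a valid integer.
substream_seed <- function(seed, i = 0L, j = 0L) {
  m <- 2147483629
  as.integer((as.numeric(seed) %% m * 48271 + i * 1000003 + j * 7919 + 12345) %% m)
}

# Evaluate `expr` under a local RNG state; the caller's stream is untouched.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Vectorized Floyd-Warshall on a matrix of edge lengths (Inf = no edge).
# Used for shortest paths inside small neighbourhood subgraphs where the
# per-call overhead of building an igraph object dominates.
fw_distances <- function(len) {
  d <- as.matrix(len)
  diag(d) <- 0
  n <- nrow(d)
  if (n <= 1) return(d)
  for (k in seq_len(n)) {
    dk <- d[, k]
    cand <- outer(dk, d[k, ], `+`)
    upd <- cand < d
    if (any(upd)) d[upd] <- cand[upd]
  }
  d
}

stop_if_not_square <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("expected a square matrix, got ", paste(dim(W), collapse = " x "))
}

check_adjacency <- function(W) {
  stop_if_not_square(W)
  if (any(!is.finite(W))) stop("adjacency contains non-finite entries")
  if (any(W < 0) || any(W > 1)) stop("adjacency weights must lie in [0, 1]")
  if (max(abs(W - t(W))) > 1e-10) stop("adjacency must be symmetric")
  invisible(W)
}
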