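# Independent oracles used across the suite. These are deliberately naive
# transcriptions, kept separate from the package's own code paths.

# Floyd-Warshall all-pairs shortest paths, literal triple loop
fw_oracle <- function(W) {
  n <- nrow(W)
  d <- ifelse(W > 0, 1 / W, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# exhaustive simple-path enumeration for tiny graphs (n <= 6)
enum_shortest <- function(W, from, to) {
  n <- nrow(W)
  best <- Inf
  recurse <- function(node, visited, len) {
    if (len >= best) return(invisible())
    if (node == to) { best <<- len; return(invisible()) }
    for (nb in seq_len(n)) {
      if (!visited[nb] && W[node, nb] > 0)
        recurse(nb, `[<-`(visited, nb, TRUE), len + 1 / W[node, nb])
    }
  }
  recurse(from, `[<-`(logical(n), from, TRUE), 0)
  best
}

# literal transcription of the weighted local-efficiency formula
eloc_oracle <- function(W) {
  n <- nrow(W)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    V <- which(W[i, ] > 0)
    k <- length(V)
    if (k < 2) next
    dsub <- fw_oracle(W[V, V, drop = FALSE])
    acc <- 0
    for (j in seq_len(k)) for (h in seq_len(k)) {
      if (j == h || !is.finite(dsub[j, h]) || dsub[j, h] == 0) next
      acc <- acc + (W[i, V[j]] * W[i, V[h]] / dsub[j, h])^(1 / 3)
    }
    vals[i] <- acc / (k * (k - 1))
  }
  mean(vals)
}

# two-tailed Monte-Carlo permutation p-value for the rank-sum statistic
perm_p_oracle <- function(a, b, n_perm = 1e5, seed = 1) {
  pooled <- c(a, b)
  na <- length(a)
  r_obs <- sum(rank(pooled)[seq_len(na)])
  e <- na * (length(pooled) + 1) / 2
  obs_dev <- abs(r_obs - e)
  set.seed(seed)
  hits <- 0L
  rk <- rank(pooled)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (abs(sum(rk[idx]) - e) >= obs_dev - 1e-9) hits <- hits + 1L
  }
  hits / n_perm
}

# exact enumeration of all group assignments (tiny n only)
exact_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  rk <- rank(pooled)
  e <- na * (length(pooled) + 1) / 2
  obs_dev <- abs(sum(rk[seq_len(na)]) - e)
  combs <- utils::combn(length(pooled), na)
  devs <- abs(colSums(matrix(rk[combs], nrow = na)) - e)
  mean(devs >= obs_dev - 1e-9)
}

# random symmetric adjacency with weights in [0, 1], zero diagonal
random_adjacency <- function(n, density = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  m <- sum(ut)
  w <- stats::runif(m) * (stats::runif(m) < density)
  W[ut] <- w
  W + t(W)
}

# small fast cohort configuration for pipeline-level tests
tiny_cohort_config <- function(seed = 1, n_subjects = 3,
                               tasks = c("FIX", "DM"), n_sources = 8,
                               duration_s = 10, planted = NULL) {
  if (is.null(planted))
    planted <- list(DM = list(planted_network("delta", rbind(c(1L, 2L)), 0.75)))
  planted <- planted[intersect(names(planted), tasks)]
  cohort_config(n_subjects = n_subjects, tasks = tasks,
                duration_s = duration_s, fs = 250, n_sources = n_sources,
                snr_db = 10, seed = seed, jitter = 0.05, planted = planted,
                bands = default_bands(c("delta", "gamma")))
}
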