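#' Node strength
#'
#' Sum of each vertex's edge weights, the weighted analogue of degree.
#'
#' @param W symmetric nonnegative adjacency matrix with zero diagonal.
#' @return Numeric vector `ns` with `ns[i] = sum_j W[i, j]`.
#' @export
node_strength <- function(W) {
  check_adjacency(W)
  rowSums(W)
}

#' Weighted shortest-path length matrix
#'
#' Edge lengths are the reciprocal weights `l_ij = 1 / w_ij` (infinite for
#' absent edges); path lengths are minimal summed lengths, computed by
#' Dijkstra's algorithm from every node. Disconnected pairs yield `Inf`;
#' the diagonal is zero.
#'
#' @param W adjacency matrix.
#' @return Symmetric matrix of shortest-path lengths.
#' @export
shortest_path_lengths <- function(W) {
  check_adjacency(W)
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, 0)   # igraph treats 0 as "no edge"
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Global efficiency
#'
#' Average inverse shortest-path length over all ordered vertex pairs, with
#' `1/Inf = 0` for disconnected pairs. For a complete graph with uniform
#' weight `w` this equals `w`.
#'
#' @param W adjacency matrix.
#' @param d optional precomputed [shortest_path_lengths()] matrix.
#' @return Scalar efficiency `>= 0`.
#' @export
global_efficiency <- function(W, d = NULL) {
  if (is.null(d)) d <- shortest_path_lengths(W)
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected ordered pairs. If some pairs
#' are disconnected the average runs over the finite pairs only and the
#' result carries attribute `disconnected = TRUE`.
#'
#' @param W adjacency matrix.
#' @param d optional precomputed distance matrix.
#' @return Scalar path length (`Inf` for an edgeless graph).
#' @export
char_path_length <- function(W, d = NULL) {
  if (is.null(d)) d <- shortest_path_lengths(W)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (!length(fin)) return(Inf)
  L <- mean(fin)
  if (length(fin) < length(off)) attr(L, "disconnected") <- TRUE
  L
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node coefficient
#' `c_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))` with `k_i`
#' the count of nonzero weights at `i` (geometric-mean triangle intensity);
#' the graph-level value is the mean over nodes with `k_i >= 2`. Reduces to
#' the binary clustering coefficient on 0/1 weights, and equals `w` on a
#' complete uniform-weight graph.
#'
#' @param W adjacency matrix with weights in `[0, 1]`.
#' @param per_node return the per-node vector instead of the mean.
#' @return Scalar in `[0, 1]`, or a per-node vector.
#' @export
clustering_coefficient <- function(W, per_node = FALSE) {
  check_adjacency(W)
  W3 <- W^(1 / 3)
  cyc3 <- diag(W3 %*% W3 %*% W3)
  k <- rowSums(W > 0)
  ci <- ifelse(k >= 2, cyc3 / (k * (k - 1)), 0)
  if (per_node) return(ci)
  if (!any(k >= 2)) return(0)
  mean(ci[k >= 2])
}

#' Weighted local efficiency (Rubinov-Sporns)
#'
#' For each node `i` with neighbourhood `N_i` (nodes with `w_ij > 0`), the
#' efficiency of the neighbourhood combines cube-root edge weights to the
#' neighbours with cube-root inverse shortest-path lengths computed within
#' the subgraph `N_i` (paths may not pass through `i`):
#' `Eloc_i = sum_{j != h in N_i} (w_ij w_ih / d_jh(N_i))^(1/3) /
#' (k_i (k_i - 1))`. Nodes of degree < 2 contribute 0, and the graph-level
#' value is the mean over all nodes.
#'
#' @param W adjacency matrix with weights in `[0, 1]`.
#' @param per_node return the per-node vector.
#' @return Scalar efficiency, or a per-node vector.
#' @export
local_efficiency <- function(W, per_node = FALSE) {
  check_adjacency(W)
  n <- nrow(W)
  lens <- ifelse(W > 0, 1 / W, Inf)
  ei <- numeric(n)
  for (i in seq_len(n)) {
    V <- which(W[i, ] > 0)
    k <- length(V)
    if (k < 2) next
    dsub <- fw_distances(lens[V, V, drop = FALSE])
    einv <- 1 / dsub
    einv[!is.finite(einv)] <- 0
    diag(einv) <- 0
    w13 <- W[i, V]^(1 / 3)
    ei[i] <- sum(outer(w13, w13) * einv^(1 / 3)) / (k * (k - 1))
  }
  if (per_node) return(ei)
  if (n < 3) return(0)
  mean(ei)
}

#' Small-worldness index
#'
#' `SWN = (CC / CC_rand) / (L / L_rand)` where the reference values are
#' means over `n_random` surrogate graphs obtained by randomly permuting
#' the off-diagonal weights of `W` while preserving symmetry and the weight
#' multiset. High values indicate simultaneously clustered and short-path
#' topology. A degenerate graph whose off-diagonal weights are all equal is
#' its own surrogate, so 1 is returned without sampling.
#'
#' @param W adjacency matrix.
#' @param n_random number of surrogate graphs (>= 10).
#' @param seed integer seed; the same `(W, seed)` always returns the same
#'   value.
#' @return Scalar index.
#' @export
small_worldness <- function(W, n_random = 100, seed = 1) {
  check_adjacency(W)
  if (n_random < 10) stop("n_random must be at least 10")
  ut <- W[upper.tri(W)]
  if (length(unique(ut)) <= 1) return(1)
  cc <- clustering_coefficient(W)
  L <- as.numeric(char_path_length(W))
  n <- nrow(W)
  sums <- with_local_seed(seed, {
    cc_r <- L_r <- numeric(n_random)
    for (r in seq_len(n_random)) {
      Ws <- matrix(0, n, n)
      Ws[upper.tri(Ws)] <- sample(ut)
      Ws <- Ws + t(Ws)
      cc_r[r] <- clustering_coefficient(Ws)
      L_r[r] <- as.numeric(char_path_length(Ws))
    }
    c(mean(cc_r), mean(L_r))
  })
  (cc / sums[1]) / (L / sums[2])
}

#' Summarize a weighted network
#'
#' Computes the requested graph metrics for one adjacency matrix, sharing
#' the shortest-path matrix between global efficiency and characteristic
#' path length.
#'
#' @param W adjacency matrix.
#' @param n_random surrogate count for [small_worldness()].
#' @param seed seed for the surrogate null.
#' @param metrics subset of `c("ns", "eglob", "eloc", "cc", "L", "swn")`.
#' @return A `graph_summary`: list with fields `ns` (vector), the requested
#'   scalar metrics (others `NA`), `n_random`, and a `disconnected` flag.
#' @export
summarize_graph <- function(W, n_random = 100, seed = 1,
                            metrics = c("ns", "eglob", "eloc", "cc", "L", "swn")) {
  check_adjacency(W)
  metrics <- match.arg(metrics, several.ok = TRUE)
  need_d <- any(c("eglob", "L", "swn") %in% metrics)
  d <- if (need_d) shortest_path_lengths(W) else NULL
  L <- if (any(c("L", "swn") %in% metrics)) char_path_length(W, d) else NA
  out <- list(
    ns = if ("ns" %in% metrics) node_strength(W) else NA,
    eglob = if ("eglob" %in% metrics) global_efficiency(W, d) else NA,
    eloc = if ("eloc" %in% metrics) local_efficiency(W) else NA,
    cc = if ("cc" %in% metrics) clustering_coefficient(W) else NA,
    L = as.numeric(L),
    swn = if ("swn" %in% metrics) small_worldness(W, n_random, seed) else NA,
    n_random = if ("swn" %in% metrics) n_random else 0L,
    disconnected = isTRUE(attr(L, "disconnected")))
  class(out) <- "graph_summary"
  out
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf(
    "graph_summary: n=%d  eglob=%.4g  eloc=%.4g  cc=%.4g  L=%.4g  swn=%.4g\n",
    length(x$ns), x$eglob, x$eloc, x$cc, x$L, x$swn))
  invisible(x)
}
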