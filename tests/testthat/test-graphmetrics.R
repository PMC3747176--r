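test_that("all metrics agree with closed forms on complete uniform graphs", {
  for (w in c(0.2, 0.5, 0.9)) {
    n <- 7
    W <- matrix(w, n, n); diag(W) <- 0
    expect_equal(node_strength(W), rep((n - 1) * w, n))
    expect_equal(global_efficiency(W), w, tolerance = 1e-12)
    expect_equal(local_efficiency(W), w, tolerance = 1e-12)
    expect_equal(clustering_coefficient(W), w, tolerance = 1e-12)
    expect_equal(as.numeric(char_path_length(W)), 1 / w, tolerance = 1e-12)
    expect_equal(small_worldness(W, 20, 1), 1)  # degenerate: no surrogates
    g <- summarize_graph(W, n_random = 20, seed = 1)
    expect_equal(g$eglob, w); expect_equal(g$eloc, w, tolerance = 1e-12)
    expect_equal(g$cc, w); expect_equal(g$L, 1 / w)
    expect_equal(g$swn, 1)
  }
})

test_that("node strength is the row sum; zero matrix gives zeros", {
  W <- random_adjacency(6, seed = 1)
  expect_equal(node_strength(W),
               vapply(1:6, function(i) sum(W[i, -i]), numeric(1)))
  expect_equal(node_strength(matrix(0, 5, 5)), rep(0, 5))
})

test_that("Dijkstra distances equal the Floyd-Warshall oracle on random graphs", {
  set.seed(42)
  for (r in 1:40) {
    n <- sample(3:12, 1)
    W <- random_adjacency(n, density = runif(1, 0.3, 1))
    d <- shortest_path_lengths(W)
    expect_equal(d, fw_oracle(W), tolerance = 1e-12)
    # metric properties
    expect_true(isSymmetric(d))
    fin <- is.finite(d)
    for (k in seq_len(n)) {
      tri <- d[, k] + rep(d[k, ], each = n)
      expect_true(all(d <= tri + 1e-9))
    }
  }
})

test_that("indirect two-hop paths beat weak direct edges", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.1
  d <- shortest_path_lengths(W)
  expect_equal(d[1, 3], 4)  # A-B-C: 2 + 2, not 1/0.1 = 10
})

test_that("global efficiency matches exhaustive path enumeration on tiny graphs", {
  set.seed(7)
  for (r in 1:5) {
    W <- random_adjacency(5, density = 0.8)
    n <- 5
    inv <- 0
    for (i in 1:n) for (j in setdiff(1:n, i)) {
      dij <- enum_shortest(W, i, j)
      inv <- inv + if (is.finite(dij) && dij > 0) 1 / dij else 0
    }
    expect_equal(global_efficiency(W), inv / (n * (n - 1)), tolerance = 1e-12)
  }
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
})

test_that("local efficiency matches the term-by-term formula oracle", {
  set.seed(19)
  for (r in 1:5) {
    W <- random_adjacency(5, density = 0.8)
    expect_equal(local_efficiency(W), eloc_oracle(W), tolerance = 1e-12)
  }
  # star graph: no neighbour-neighbour links
  S <- matrix(0, 5, 5); S[1, 2:5] <- S[2:5, 1] <- 0.8
  expect_equal(local_efficiency(S), 0)
})

test_that("weighted clustering reduces to the binary coefficient on 0/1 weights", {
  set.seed(31)
  for (r in 1:5) {
    B <- random_adjacency(8, density = 0.6) > 0.3
    B <- B * 1
    g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
    ours <- clustering_coefficient(B, per_node = TRUE)
    ref <- igraph::transitivity(g, type = "local", isolates = "zero")
    deg <- rowSums(B)
    expect_equal(ours[deg >= 2], ref[deg >= 2], tolerance = 1e-12)
  }
  # triangle-free graph: a 4-cycle
  C4 <- matrix(0, 4, 4)
  C4[1, 2] <- C4[2, 3] <- C4[3, 4] <- C4[4, 1] <- 0.7
  C4 <- pmax(C4, t(C4))
  expect_equal(clustering_coefficient(C4), 0)
})

test_that("characteristic path length handles trivial and random cases", {
  W2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(as.numeric(char_path_length(W2)), 2)
  W <- random_adjacency(6, seed = 3, density = 0.9)
  dref <- fw_oracle(W)
  off <- dref[row(dref) != col(dref)]
  expect_equal(as.numeric(char_path_length(W)), mean(off[is.finite(off)]),
               tolerance = 1e-12)
})

test_that("small-worldness exceeds 1 on a shortcut ring lattice and is seeded", {
  n <- 20
  W <- matrix(0, n, n)
  for (i in 1:n) for (s in 1:2) {
    j <- ((i + s - 1) %% n) + 1
    W[i, j] <- W[j, i] <- 0.9
  }
  set.seed(4)
  for (s in 1:4) {
    ij <- sample(n, 2)
    W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- 0.9
  }
  s1 <- small_worldness(W, n_random = 50, seed = 10)
  expect_gt(s1, 1)
  expect_identical(s1, small_worldness(W, n_random = 50, seed = 10))
  expect_error(small_worldness(W, n_random = 5), "at least 10")
})

test_that("metrics scale correctly under uniform weight scaling", {
  W <- random_adjacency(10, seed = 12, density = 0.8)
  for (cs in c(0.3, 0.7)) {
    expect_equal(node_strength(cs * W), cs * node_strength(W))
    expect_equal(global_efficiency(cs * W), cs * global_efficiency(W),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(cs * W), cs * local_efficiency(W),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(cs * W),
                 cs * clustering_coefficient(W), tolerance = 1e-12)
    expect_equal(as.numeric(char_path_length(cs * W)),
                 as.numeric(char_path_length(W)) / cs, tolerance = 1e-12)
    expect_equal(small_worldness(cs * W, 20, 3), small_worldness(W, 20, 3),
                 tolerance = 1e-12)
  }
})

test_that("relabeling nodes permutes NS and leaves scalar metrics unchanged", {
  W <- random_adjacency(9, seed = 21, density = 0.8)
  set.seed(6)
  p <- sample(9)
  Wp <- W[p, p]
  expect_equal(node_strength(Wp), node_strength(W)[p])
  expect_equal(global_efficiency(Wp), global_efficiency(W), tolerance = 1e-12)
  expect_equal(local_efficiency(Wp), local_efficiency(W), tolerance = 1e-12)
  expect_equal(clustering_coefficient(Wp), clustering_coefficient(W),
               tolerance = 1e-12)
  expect_equal(as.numeric(char_path_length(Wp)),
               as.numeric(char_path_length(W)), tolerance = 1e-12)
})

test_that("summarize_graph fields match the standalone operations", {
  W <- random_adjacency(8, seed = 33, density = 0.9)
  g <- summarize_graph(W, n_random = 20, seed = 2)
  expect_equal(g$ns, node_strength(W))
  expect_equal(g$eglob, global_efficiency(W))
  expect_equal(g$eloc, local_efficiency(W))
  expect_equal(g$cc, clustering_coefficient(W))
  expect_equal(g$L, as.numeric(char_path_length(W)))
  expect_equal(g$swn, small_worldness(W, 20, 2))
  # zero matrix degenerates gracefully
  z <- summarize_graph(matrix(0, 5, 5), metrics = c("ns", "eglob", "cc"))
  expect_equal(z$ns, rep(0, 5)); expect_equal(z$eglob, 0)
  expect_equal(z$cc, 0)
})
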