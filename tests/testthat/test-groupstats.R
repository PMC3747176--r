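test_that("normality screening is calibrated on normal and skewed samples", {
  set.seed(1)
  res_norm <- replicate(100, normality_screen(rnorm(24))["shapiro_p"])
  expect_gte(mean(res_norm > 0.05), 0.90)
  res_skew <- replicate(100, normality_screen(rlnorm(24, sdlog = 1.5))["shapiro_p"])
  expect_gte(mean(res_skew < 0.01), 0.90)
  # both tests are returned
  out <- normality_screen(rnorm(24))
  expect_named(out, c("shapiro_p", "ks_p"))
  expect_true(all(out >= 0 & out <= 1))
  # degenerate inputs
  expect_error(normality_screen(c(1, 2)), "n >= 3")
  expect_error(normality_screen(rep(1, 10)), "constant")
})

test_that("U statistic and asymptotic p match the exact-enumeration oracle", {
  u <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(u$U, 0)
  p_exact <- exact_p_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p_exact, 0.1)  # 2 of the 20 rank assignments are as extreme
  expect_lt(abs(u$p - p_exact), 0.06)

  # complete overlap
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney_u(rep(2, 4), rep(2, 5))$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("asymptotic p is within 0.01 of the permutation p at n = 24 per group", {
  set.seed(77)
  for (r in 1:4) {
    a <- rnorm(24, mean = runif(1, -0.5, 0.5))
    b <- rnorm(24)
    u <- mann_whitney_u(a, b)
    p_perm <- perm_p_oracle(a, b, n_perm = 2e4, seed = r)
    expect_lt(abs(u$p - p_perm), 0.01)
  }
})

test_that("BH step-up matches the hand-computed adjustment and is monotone", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_equal(res$p_adj, rep(0.04, 4))  # min over k>=i of p_(k) * m / k
  expect_true(all(res$reject))

  expect_equal(bh_fdr(0.03)$p_adj, 0.03)

  set.seed(2)
  p <- sort(runif(20))
  expect_true(all(diff(bh_fdr(p)$p_adj) >= 0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH controls the family-level error rate on fully-null families", {
  # reduced-size null calibration: families of 10 U tests on null samples
  set.seed(99)
  n_rep <- 300
  any_rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    p <- replicate(10, mann_whitney_u(rnorm(8), rnorm(8))$p)
    any_rej[r] <- any(bh_fdr(p, 0.05)$reject)
  }
  expect_lte(mean(any_rej), 0.06)
})

test_that("compare_tasks tests all 6 pairs with FDR within (band, metric)", {
  set.seed(11)
  summaries <- expand.grid(subject = sprintf("S%02d", 1:10),
                           task = c("FIX", "DL", "SM", "DM"),
                           band = "delta", stringsAsFactors = FALSE)
  summaries$eglob <- rnorm(nrow(summaries), 0.2, 0.02)
  # plant a DM shift
  summaries$eglob[summaries$task == "DM"] <-
    summaries$eglob[summaries$task == "DM"] + 0.2
  st <- compare_tasks(summaries, "eglob", "delta")
  expect_equal(nrow(st), 6)  # C(4, 2)
  expect_true(all(st$p_fdr >= st$p_raw))
  dm_rows <- st$task_a == "DM" | st$task_b == "DM"
  expect_true(all(st$reject_at_05[dm_rows]))
  expect_false(any(st$reject_at_05[!dm_rows]))
  # means mirror the group values
  expect_equal(st$mean_a[1], mean(summaries$eglob[summaries$task == st$task_a[1]]))
  # a task with < 2 subjects is skipped with a warning
  few <- summaries[!(summaries$task == "DL" & summaries$subject != "S01"), ]
  expect_warning(compare_tasks(few, "eglob", "delta"), "DL")
})

test_that("node-strength contrasts recover planted nodes at the source level", {
  # planted coupling confined to nodes {1, 2}: only those nodes should be
  # flagged when coherence is computed in source space (no inverse smearing)
  hits <- matrix(FALSE, 10, 2); false_extra <- logical(10)
  for (s in 1:10) {
    cfg <- cohort_config(n_subjects = 8, tasks = c("FIX", "DM"),
                         duration_s = 10, fs = 250, n_sources = 12,
                         snr_db = Inf, seed = 100 + s, jitter = 0.05,
                         planted = list(DM = list(
                           planted_network("delta", rbind(c(1L, 2L)), 0.8))),
                         bands = default_bands("delta"))
    ns_by_task <- list()
    for (task in cfg$tasks) {
      ns <- t(vapply(seq_len(cfg$n_subjects), function(subj) {
        X <- generate_sources(cfg, subj, task)$rec$data
        W <- msc_matrix(X, 250, spectral_config(), cfg$bands)[[1]]
        node_strength(W)
      }, numeric(12)))
      ns_by_task[[task]] <- ns
    }
    m <- compare_node_strength(ns_by_task$FIX, ns_by_task$DM, "FIX", "DM")
    hits[s, ] <- m$reject[1:2]
    false_extra[s] <- any(m$reject[3:12])
  }
  expect_gte(mean(hits), 0.8)
  expect_lte(mean(false_extra), 0.2)

  # identical groups: no rejections expected
  set.seed(5)
  ns0 <- matrix(rnorm(8 * 12), 8)
  m0 <- compare_node_strength(ns0, ns0, "A", "A")
  expect_false(any(m0$reject))
  expect_length(m0$p_raw, 12)
  expect_error(compare_node_strength(ns0, ns0[, 1:5]), "mismatch")
})

test_that("edge difference maps subtract control, threshold and antisymmetrize", {
  set.seed(3)
  A <- random_adjacency(6, density = 1)
  B <- random_adjacency(6, density = 1)
  # task = control: zero map
  z <- edge_difference_map(A, A, 0.1)
  expect_true(all(z$diff == 0) && all(z$display == 0))
  # swap negates
  d1 <- edge_difference_map(A, B, 0.1)
  d2 <- edge_difference_map(B, A, 0.1)
  expect_equal(d1$diff, -d2$diff)
  expect_equal(d1$display, -d2$display)
  # threshold zeroes sub-threshold entries, keeps the full matrix
  expect_true(all(d1$display[abs(d1$diff) < 0.1] == 0))
  expect_equal(d1$diff, A - B)
  expect_error(edge_difference_map(A, B[1:5, 1:5], 0.1), "shape")
  # per-band display defaults
  thr <- edge_threshold_defaults()
  expect_equal(unname(thr[c("delta", "theta", "alpha1", "alpha2")]),
               rep(0.10, 4))
  expect_equal(unname(thr[c("beta", "gamma")]), rep(0.05, 2))
})
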