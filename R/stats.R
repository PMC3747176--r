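#' Normality screening
#'
#' Shapiro-Wilk and Lilliefors (Kolmogorov-Smirnov with estimated
#' parameters) tests of composite normality, used to justify the
#' nonparametric comparison path. The Lilliefors test requires at least 5
#' observations; below that `ks_p` is `NA` with a warning.
#'
#' @param x numeric sample of length >= 3, not constant.
#' @return Named numeric vector `c(shapiro_p, ks_p)`.
#' @export
normality_screen <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("normality screening requires n >= 3")
  if (stats::sd(x) == 0) stop("constant sample: normality tests undefined")
  sp <- stats::shapiro.test(x)$p.value
  kp <- if (length(x) >= 5) nortest::lillie.test(x)$p.value else {
    warning("Lilliefors test requires n >= 5; returning NA")
    NA_real_
  }
  c(shapiro_p = sp, ks_p = kp)
}

#' Asymptotic two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The p-value comes from
#' the normal approximation with tie correction and continuity correction;
#' the reported statistic is `min(U_a, U_b)`, the conventional form. If
#' every value in both samples is identical the groups overlap completely
#' and `p = 1`.
#'
#' @param a,b numeric samples (each n >= 1).
#' @return List with elements `U` and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  if (length(unique(c(a, b))) == 1)
    return(list(U = na * nb / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  Ua <- unname(wt$statistic)
  list(U = min(Ua, na * nb - Ua), p = min(1, wt$p.value))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values `p_adj(i) = min_{k >= i} p_(k) * m / k` with
#' enforced monotonicity; hypotheses with `p_adj <= q` are rejected.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @param q nominal FDR level (default 0.05).
#' @return List with `p_adj` and logical `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, reject = !is.na(p_adj) & p_adj <= q)
}

#' Pairwise task comparisons of one graph metric in one band
#'
#' Tests all unordered task pairs with the asymptotic two-tailed
#' Mann-Whitney U test and applies Benjamini-Hochberg FDR across the
#' pairwise family within this (band, metric) cell. Group means and SDs are
#' reported alongside.
#'
#' @param summaries data.frame with columns `subject`, `task`, `band` and
#'   one column per scalar metric (as produced by the pipeline).
#' @param metric metric column name (e.g. `"eglob"`).
#' @param band band name to subset on.
#' @param q FDR level.
#' @return data.frame with one row per task pair: band, metric, task_a,
#'   task_b, mean/sd per group, `U`, `p_raw`, `p_fdr`, `reject_at_05`.
#' @export
compare_tasks <- function(summaries, metric, band, q = 0.05) {
  df <- summaries[summaries$band == band, , drop = FALSE]
  if (!metric %in% names(df)) stop("no metric column named ", metric)
  tasks <- unique(df$task)
  counts <- table(df$task)
  ok <- names(counts)[counts >= 2]
  skipped <- setdiff(tasks, ok)
  if (length(skipped))
    warning("task(s) with < 2 subjects skipped: ",
            paste(skipped, collapse = ", "))
  tasks <- ok
  if (length(tasks) < 2) stop("need at least two tasks with >= 2 subjects")
  pairs <- utils::combn(tasks, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ta <- pairs[1, j]; tb <- pairs[2, j]
    va <- df[[metric]][df$task == ta]
    vb <- df[[metric]][df$task == tb]
    u <- mann_whitney_u(va, vb)
    data.frame(band = band, metric = metric, task_a = ta, task_b = tb,
               mean_a = mean(va), sd_a = stats::sd(va),
               mean_b = mean(vb), sd_b = stats::sd(vb),
               U = u$U, p_raw = u$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p_raw, q)
  out$p_fdr <- adj$p_adj
  out$reject_at_05 <- adj$reject
  out
}

#' Per-node node-strength contrast between two tasks
#'
#' For each node, compares the subjects' node strengths between the two
#' tasks with the Mann-Whitney U test, then controls the FDR across nodes
#' within this one contrast.
#'
#' @param ns_a,ns_b numeric matrices, subjects x nodes, for the two tasks.
#' @param task_a,task_b labels used in the contrast name.
#' @param q FDR level.
#' @return A `node_stat_map`: list with `contrast`, `p_raw`, `p_fdr`,
#'   `reject` (all length = node count).
#' @export
compare_node_strength <- function(ns_a, ns_b, task_a = "A", task_b = "B",
                                  q = 0.05) {
  ns_a <- as.matrix(ns_a); ns_b <- as.matrix(ns_b)
  if (ncol(ns_a) != ncol(ns_b))
    stop("node-count mismatch: ", ncol(ns_a), " vs ", ncol(ns_b))
  p <- vapply(seq_len(ncol(ns_a)), function(j)
    mann_whitney_u(ns_a[, j], ns_b[, j])$p, numeric(1))
  adj <- bh_fdr(p, q)
  structure(list(contrast = paste(task_a, "vs", task_b),
                 p_raw = p, p_fdr = adj$p_adj, reject = adj$reject),
            class = "node_stat_map")
}

#' Task-minus-control edge difference map
#'
#' Subtracts the control condition's mean adjacency matrix from the task's
#' and zeroes entries below the display threshold in absolute value; the
#' full unthresholded difference is retained alongside. Swapping the two
#' inputs negates the map.
#'
#' @param mean_task,mean_control mean adjacency matrices of equal shape.
#' @param threshold display threshold (see [edge_threshold_defaults()]).
#' @return An `edge_diff_map`: list with `diff` (full matrix), `display`
#'   (thresholded) and `threshold`.
#' @export
edge_difference_map <- function(mean_task, mean_control, threshold = 0.1) {
  if (!all(dim(mean_task) == dim(mean_control)))
    stop("shape mismatch between task and control matrices")
  D <- mean_task - mean_control
  disp <- D
  disp[abs(disp) < threshold] <- 0
  structure(list(diff = D, display = disp, threshold = threshold),
            class = "edge_diff_map")
}

#' Mean adjacency matrix over a list of matrices
#'
#' @param mats list of equally sized matrices.
#' @return Elementwise mean matrix.
#' @export
mean_adjacency <- function(mats) {
  stopifnot(length(mats) >= 1)
  Reduce(`+`, mats) / length(mats)
}
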