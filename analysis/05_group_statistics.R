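#!/usr/bin/env Rscript
# Pairwise task contrasts of the graph metrics: normality screening,
# Mann-Whitney U tests with BH-FDR per (band, metric), per-node strength
# contrasts, and task-minus-FIX edge difference maps.

library(cortexnet)

summaries <- read.table("results/graph_summaries.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
ns_long <- read.table("scratch/analysis/node_strength.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)

# nonparametric path justification: screen each (band, task) cell
scr <- do.call(rbind, lapply(split(summaries, paste(summaries$band,
                                                    summaries$task)),
  function(d) data.frame(band = d$band[1], task = d$task[1],
                         shapiro_p = normality_screen(d$eglob)[["shapiro_p"]])))
cat("normality screening (Eglob): min Shapiro p =",
    signif(min(scr$shapiro_p), 3), "\n")

stats <- list()
for (b in unique(summaries$band)) for (m in c("eglob", "eloc", "swn"))
  stats[[paste(b, m)]] <- compare_tasks(summaries, m, b, q = 0.05)
scalar <- do.call(rbind, stats); rownames(scalar) <- NULL
write.table(scalar, "results/stats_scalar.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("\nFDR-significant pairwise differences (q = 0.05):\n")
print(scalar[scalar$reject_at_05,
             c("band", "metric", "task_a", "task_b", "p_fdr")])

# per-node NS contrast, DM vs FIX, within each band
for (b in unique(ns_long$band)) {
  sub <- ns_long[ns_long$band == b, ]
  mk <- function(task) {
    d <- sub[sub$task == task, ]
    t(vapply(split(d$ns, d$subject), identity,
             numeric(max(d$node))))
  }
  m <- compare_node_strength(mk("FIX"), mk("DM"), "FIX", "DM")
  cat(b, "band, DM vs FIX: significant nodes:",
      paste(which(m$reject), collapse = " "), "\n")
}

# edge difference maps vs the control task
adj_idx <- read.table("scratch/analysis/adjacency/index.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
readW <- function(subject, band, task)
  as.matrix(read.table(file.path("scratch/analysis/adjacency",
                                 paste(subject, band, task, sep = "_") |>
                                   paste0(".tsv")), sep = "\t"))
thr <- edge_threshold_defaults()
for (b in unique(adj_idx$band)) {
  subs <- unique(adj_idx$subject)
  m_dm <- mean_adjacency(lapply(subs, readW, band = b, task = "DM"))
  m_fx <- mean_adjacency(lapply(subs, readW, band = b, task = "FIX"))
  em <- edge_difference_map(m_dm, m_fx,
                            if (b %in% names(thr)) thr[[b]] else 0.1)
  n_strong <- sum(em$display[upper.tri(em$display)] > 0)
  cat(b, "band DM-FIX: ", n_strong,
      "edges above the display threshold", em$threshold, "\n")
  write.table(signif(em$diff, 8),
              file.path("results", paste0("edge_diff_", b, "_DM.tsv")),
              sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
}
cat("wrote results/stats_scalar.tsv and edge difference maps\n")
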