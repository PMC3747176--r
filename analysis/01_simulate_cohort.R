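#!/usr/bin/env Rscript
# Simulate a reduced-scale synthetic EEG cohort (24 subjects x 4 tasks,
# 30 cortical sources, 10 s @ 500 Hz) with a delta-band coupling increase
# planted only in the DM condition, and write it to scratch/analysis/cohort/ as
# TSV matrices with JSON sidecars plus a ground-truth manifest.

library(cortexnet)

seed <- 101
cfg <- cohort_config(n_sources = 30,
                     bands = default_bands(c("delta", "gamma")),
                     seed = seed)
lf <- build_lead_field(28, cfg$n_sources, seed = seed)
cat("lead field:", nrow(lf$A), "sensors x", ncol(lf$A), "dipoles\n")

cohort <- generate_cohort(cfg, lf)
cat("generated", length(cohort), "recordings (",
    cfg$n_subjects, "subjects x", length(cfg$tasks), "tasks )\n")

manifest <- write_cohort(cohort, "scratch/analysis/cohort")
cat("wrote", length(list.files("scratch/analysis/cohort", "\\.tsv$")),
    "TSV recordings +", basename(manifest), "\n")

# the planted truth for subject 1, DM: three delta edges, jittered mixing
truth <- attr(cohort, "truth")[["S01.DM"]]
cat("S01/DM planted delta edges (mixing after subject jitter):\n")
print(cbind(truth[[1]]$edges, mixing = round(truth[[1]]$mixing, 3)))
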