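test_that("planted mixing controls in-band coherence (MSC ~ a^2)", {
  sc <- spectral_config()
  band <- default_bands("delta")
  mk <- function(a, seed = 1, dur = 120) {
    cfg <- cohort_config(n_subjects = 2, tasks = "DM", duration_s = dur,
                         fs = 500, n_sources = 4, snr_db = Inf, seed = seed,
                         jitter = 0,
                         planted = list(DM = list(
                           planted_network("delta", rbind(c(1L, 2L)), a))))
    generate_sources(cfg, 1, "DM")$rec$data
  }
  # a = 1: identical shared component, near-perfect in-band coherence
  x1 <- mk(1)
  expect_gt(msc_pair(x1[1, ], x1[2, ], 500, sc, band), 0.95)
  # a = 0: independent signals, MSC near the estimator bias floor
  x0 <- mk(0)
  expect_lt(msc_pair(x0[1, ], x0[2, ], 500, sc, band), 0.05)
  # a = 0.5 on a 120 s record: MSC ~ a^2 = 0.25 within +/- 0.03
  xh <- mk(0.5)
  expect_equal(msc_pair(xh[1, ], xh[2, ], 500, sc, band), 0.25,
               tolerance = 0.03 / 0.25)
})

test_that("cross-band leakage stays within the independent-noise bias envelope", {
  cfg <- cohort_config(n_subjects = 2, tasks = "DM", duration_s = 10,
                       fs = 500, n_sources = 20, snr_db = Inf, seed = 3,
                       jitter = 0,
                       planted = list(DM = list(
                         planted_network("delta", rbind(c(1L, 2L)), 0.75))))
  X <- generate_sources(cfg, 1, "DM")$rec$data
  mats <- msc_matrix(X, 500, spectral_config(), default_bands())
  k_bias <- 1 / 19
  # planted band clearly elevated for the planted pair only
  expect_gt(mats$delta[1, 2], 0.4)
  # distant bands: mean off-diagonal MSC stays near the bias floor
  for (b in c("alpha1", "alpha2", "beta", "gamma")) {
    off <- mats[[b]][upper.tri(mats[[b]])]
    expect_lt(mean(off), k_bias + 0.03)
  }
})

test_that("overlapping planted edges in one band are rejected", {
  expect_error(
    cohort_config(n_sources = 8, planted = list(DM = list(
      planted_network("delta", rbind(c(1L, 2L), c(1L, 3L)), 0.5)))) |>
      generate_sources(1, "DM"),
    "overlapping")
})

test_that("sensor projection is exact without noise and deterministic with it", {
  src <- structure(list(data = rbind(c(1, 2, 3), c(4, 5, 6)), fs = 10,
                        source_ids = c("a", "b"), subject = "S01",
                        task = "FIX"), class = "source_recording")
  lf <- list(A = rbind(c(1, 0), c(0, 2)), sensor_labels = c("e1", "e2"))
  out <- project_to_sensors(src, lf, snr_db = Inf)
  expect_identical(out$data, lf$A %*% src$data)

  # dimension mismatch
  bad <- list(A = matrix(1, 2, 3), sensor_labels = c("e1", "e2"))
  expect_error(project_to_sensors(src, bad), "sources")

  # configured absolute noise power: variance within 5% over 60 s
  zero_src <- structure(list(data = matrix(0, 2, 600 * 50), fs = 50,
                             source_ids = c("a", "b"), subject = "S01",
                             task = "FIX"), class = "source_recording")
  nz <- project_to_sensors(zero_src, lf, snr_db = 10, seed = 5, noise_sd = 1)
  expect_equal(stats::var(as.vector(nz$data)), 1, tolerance = 0.05)
  # zero signal with signal-relative SNR alone is degenerate
  expect_error(project_to_sensors(zero_src, lf, snr_db = 10), "zero power")

  # fixed seed: bit-identical noise
  a <- project_to_sensors(src, lf, snr_db = 10, seed = 9)
  b <- project_to_sensors(src, lf, snr_db = 10, seed = 9)
  expect_identical(a$data, b$data)
})

test_that("cohort generation yields n_subjects x n_tasks recordings, deterministically", {
  cfg <- cohort_config(n_subjects = 24, tasks = c("FIX", "DL", "SM", "DM"),
                       duration_s = 2, fs = 250, n_sources = 8, snr_db = 10,
                       seed = 2, planted = default_planted(),
                       bands = default_bands(), window_s = 1)
  lf <- build_lead_field(10, 8, seed = 1)
  coh <- generate_cohort(cfg, lf)
  expect_length(coh, 96)
  idx <- attr(coh, "index")
  expect_equal(nrow(idx), 96)
  expect_setequal(unique(idx$task), c("FIX", "DL", "SM", "DM"))

  # smallest admissible cohort
  cfg2 <- tiny_cohort_config(n_subjects = 2, tasks = "FIX", duration_s = 10)
  lf2 <- build_lead_field(6, 8, seed = 1)
  expect_length(generate_cohort(cfg2, lf2), 2)

  # same config, same seed: identical cohort
  coh2 <- generate_cohort(cfg, lf)
  expect_identical(coh[["S07.DM"]]$data, coh2[["S07.DM"]]$data)
  expect_identical(attr(coh, "truth"), attr(coh2, "truth"))
})

test_that("subject jitter perturbs mixing within the configured bounds", {
  cfg <- tiny_cohort_config(seed = 4, n_subjects = 6)
  mix <- vapply(1:6, function(s)
    generate_sources(cfg, s, "DM")$planted[[1]]$mixing, numeric(1))
  expect_true(all(abs(mix - 0.75) <= 0.05 + 1e-12))
  expect_gt(stats::sd(mix), 0)  # heterogeneity actually present
})

test_that("cohort TSV export round-trips through ingestion", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_subjects = 2, tasks = c("FIX", "DM"),
                       duration_s = 10, fs = 500, n_sources = 6, snr_db = 10,
                       seed = 6, planted = list(DM = list(
                         planted_network("delta", rbind(c(1L, 2L)), 0.6))))
  lf <- build_lead_field(28, 6, seed = 1)
  coh <- generate_cohort(cfg, lf)
  manifest <- write_cohort(coh, dir)
  expect_true(file.exists(manifest))
  back <- ingest_recordings(dir)
  expect_length(back, 4)
  expect_equal(back[["S01.DM"]]$data, coh[["S01.DM"]]$data,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back[["S01.DM"]]$labels, coh[["S01.DM"]]$labels)
})
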