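#' Band-limited unit-variance Gaussian noise
#'
#' White Gaussian noise passed through a zero-phase band-pass: 4th-order
#' Butterworth high- and low-pass sections applied forward-backward
#' ([signal::filtfilt]) with one second of padding trimmed from each end,
#' then standardized to zero mean and unit variance. The filter corners are
#' placed `margin` Hz outside `[f_lo, f_hi)` so that the zero-phase response
#' is essentially flat across the analysis bins of that band (a
#' forward-backward filter leaves only quarter power at its nominal corner).
#'
#' @param n number of samples to return.
#' @param fs sampling rate (Hz).
#' @param f_lo,f_hi band edges in Hz.
#' @param margin corner offset in Hz (default 0.25).
#' @return Numeric vector of length `n`.
#' @export
band_limited_noise <- function(n, fs, f_lo, f_hi, margin = 0.25) {
  stopifnot(n > 0, fs > 0, f_lo > 0, f_hi > f_lo, f_hi <= fs / 2)
  pad <- fs  # 1 s padding per side against filter transients
  x <- stats::rnorm(n + 2 * pad)
  y <- bandpass_zero_phase(x, fs, f_lo, f_hi, margin)
  y <- y[(pad + 1):(pad + n)]
  (y - mean(y)) / stats::sd(y)
}

# zero-phase band-pass: cascaded 4th-order Butterworth HP then LP, filtfilt
bandpass_zero_phase <- function(x, fs, f_lo, f_hi, margin = 0.25) {
  lo <- max(f_lo - margin, 0.05)
  hi <- min(f_hi + margin, fs / 2 * 0.99)
  hp <- signal::butter(4, lo / (fs / 2), type = "high")
  lp <- signal::butter(4, hi / (fs / 2), type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' Define a planted coupling network for one frequency band
#'
#' A planted network declares which source pairs share a band-limited common
#' component and how strongly. For an edge with mixing `a`, each member
#' source carries `sqrt(a) * s + sqrt(1 - a) * n_i` inside the band, where
#' `s` is the edge's shared unit-variance process and `n_i` independent
#' unit-variance band noise; the expected in-band magnitude-squared
#' coherence between the pair is then `a^2`.
#'
#' @param band band name (must appear in the cohort's band table).
#' @param edges two-column integer matrix of unordered source pairs.
#' @param mixing shared-variance fraction in `[0, 1]`, recycled per edge.
#' @return An object of class `planted_network`.
#' @export
planted_network <- function(band, edges, mixing) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
  mixing <- rep_len(as.numeric(mixing), nrow(edges))
  if (any(mixing < 0 | mixing > 1)) stop("mixing must lie in [0, 1]")
  structure(list(band = band, edges = edges, mixing = mixing),
            class = "planted_network")
}

#' Default planted coupling: difficult-multiplication delta boost
#'
#' The default study conditions plant three disjoint delta-band edges among
#' sources 1-6, present only in the DM task, emulating a condition-specific
#' increase in low-frequency cortical coupling.
#'
#' @param mixing shared-variance fraction (default 0.75).
#' @return Named list mapping task label to a list of [planted_network()]s.
#' @export
default_planted <- function(mixing = 0.75) {
  list(DM = list(planted_network("delta",
                                 rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
                                 mixing)))
}

#' Configure a synthetic EEG cohort
#'
#' Defines the study conditions of a simulated cohort: 24 subjects by
#' default, the four task labels FIX/DL/SM/DM, 10-second segments at 500 Hz,
#' and a per-task map of planted band-specific coupling networks.
#' Between-subject variation comes from perturbing each edge's mixing by a
#' subject-specific uniform jitter.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param tasks ordered character vector of task labels.
#' @param duration_s segment duration in seconds.
#' @param fs sampling rate in Hz.
#' @param n_sources number of cortical sources to simulate.
#' @param snr_db sensor signal-to-noise ratio in dB (total signal power over
#'   noise power at the sensors); `Inf` disables sensor noise.
#' @param seed master integer seed; every recording is a deterministic
#'   function of `(seed, subject, task)`.
#' @param jitter half-width of the per-subject uniform mixing perturbation.
#' @param planted named list mapping task label to a list of
#'   [planted_network()] objects; tasks may be absent (no planted coupling).
#' @param bands band table ([default_bands()]) used to resolve band names.
#' @param window_s Welch window length (s) of the downstream spectral
#'   analysis; segments must last at least two windows.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 24, tasks = c("FIX", "DL", "SM", "DM"),
                          duration_s = 10, fs = 500, n_sources = 258,
                          snr_db = 10, seed = 1, jitter = 0.05,
                          planted = default_planted(), bands = default_bands(),
                          window_s = 1) {
  stopifnot(n_subjects >= 2, length(tasks) >= 1, duration_s > 0, fs > 0)
  if (duration_s * fs < 2 * window_s * fs)
    stop("segments must span at least two Welch windows")
  unknown <- setdiff(names(planted), tasks)
  if (length(unknown))
    stop("planted networks reference unknown task(s): ",
         paste(unknown, collapse = ", "))
  for (task in names(planted)) for (net in planted[[task]]) {
    if (!inherits(net, "planted_network")) stop("planted entries must be planted_network objects")
    if (!net$band %in% bands$name) stop("unknown band in planted network: ", net$band)
    if (max(net$edges) > n_sources) stop("planted edge references source beyond n_sources")
  }
  structure(list(n_subjects = as.integer(n_subjects), tasks = tasks,
                 duration_s = duration_s, fs = fs,
                 n_sources = as.integer(n_sources), snr_db = snr_db,
                 seed = as.integer(seed), jitter = jitter, planted = planted,
                 bands = bands, window_s = window_s),
            class = "cohort_config")
}

# per-band check that no source belongs to two planted edges
check_planted_overlap <- function(nets) {
  bands <- unique(vapply(nets, `[[`, "", "band"))
  for (b in bands) {
    members <- unlist(lapply(nets[vapply(nets, `[[`, "", "band") == b],
                             function(net) as.vector(net$edges)))
    if (anyDuplicated(members))
      stop("overlapping planted edges on source(s) ",
           paste(unique(members[duplicated(members)]), collapse = ", "),
           " within band ", b)
  }
  invisible(TRUE)
}

#' Simulate one subject-task source recording with planted coupling
#'
#' Each source starts as independent broadband (white) background. For every
#' planted edge in band B that a source belongs to, the background is
#' band-stopped in B (the zero-phase band-pass of the background is
#' subtracted) and the in-band mixture `sqrt(a) s_e + sqrt(1 - a) n_i` is
#' added, with `a` the edge's mixing after the subject's jitter. The result
#' is deterministic given `(config$seed, subject, task)`.
#'
#' @param config a [cohort_config()].
#' @param subject subject index in `1:n_subjects`.
#' @param task task label from `config$tasks`.
#' @return List with elements `rec` (a `source_recording`: `data` is an
#'   `n_sources x n_samples` matrix, plus `fs` and `source_ids`) and
#'   `planted` (the planted networks with subject-jittered mixing).
#' @export
generate_sources <- function(config, subject, task) {
  stopifnot(inherits(config, "cohort_config"))
  subject <- as.integer(subject)
  if (subject < 1 || subject > config$n_subjects) stop("subject out of range")
  task_idx <- match(task, config$tasks)
  if (is.na(task_idx)) stop("unknown task: ", task)

  nets <- config$planted[[task]]
  if (!is.null(nets)) check_planted_overlap(nets)

  n <- as.integer(round(config$duration_s * config$fs))
  n_src <- config$n_sources

  # subject-level jitter: stable across tasks for a given subject
  nets <- jitter_mixing(config, subject, task, nets)

  rec_seed <- substream_seed(config$seed, subject, task_idx)
  data <- with_local_seed(rec_seed, {
    X <- matrix(stats::rnorm(n_src * n), nrow = n_src)
    for (net in seq_along(nets)) {
      pn <- nets[[net]]
      bi <- match(pn$band, config$bands$name)
      f_lo <- config$bands$f_lo[bi]; f_hi <- config$bands$f_hi[bi]
      for (e in seq_len(nrow(pn$edges))) {
        a <- pn$mixing[e]
        s_shared <- band_limited_noise(n, config$fs, f_lo, f_hi)
        for (i in pn$edges[e, ]) {
          X[i, ] <- X[i, ] - bandpass_zero_phase(X[i, ], config$fs, f_lo, f_hi)
          ni <- band_limited_noise(n, config$fs, f_lo, f_hi)
          X[i, ] <- X[i, ] + sqrt(a) * s_shared + sqrt(1 - a) * ni
        }
      }
    }
    X
  })
  rec <- structure(list(data = data, fs = config$fs,
                        source_ids = sprintf("src%03d", seq_len(n_src)),
                        subject = sprintf("S%02d", subject), task = task),
                   class = "source_recording")
  list(rec = rec, planted = nets)
}

# apply per-subject uniform mixing jitter, clamped to [0, 1]
jitter_mixing <- function(config, subject, task, nets) {
  if (is.null(nets) || config$jitter <= 0) return(nets)
  jseed <- substream_seed(config$seed, subject, 999983L)
  with_local_seed(jseed, {
    # draw jitters for every planted edge in config order so a subject's
    # perturbation for a given edge does not depend on which task is asked
    draws <- list()
    for (tk in names(config$planted)) {
      m <- sum(vapply(config$planted[[tk]], function(x) nrow(x$edges), 0L))
      draws[[tk]] <- stats::runif(m, -config$jitter, config$jitter)
    }
    tk_draws <- draws[[task]]
    off <- 0L
    for (k in seq_along(nets)) {
      ne <- nrow(nets[[k]]$edges)
      nets[[k]]$mixing <- pmin(1, pmax(0, nets[[k]]$mixing +
                                            tk_draws[off + seq_len(ne)]))
      off <- off + ne
    }
    nets
  })
}

#' Project source activity to the sensors with additive white noise
#'
#' Computes `lf$A %*% src$data` and adds white Gaussian sensor noise scaled
#' so that total signal power over noise power equals `snr_db` (in dB).
#' `snr_db = Inf` disables noise. When the projected signal has zero power
#' the signal-relative definition is degenerate; pass `noise_sd` to set the
#' noise standard deviation directly in that case (or to override the SNR
#' scaling in general).
#'
#' @param src a `source_recording`.
#' @param lf a [build_lead_field()] result (or any list with matrix `A` and
#'   `sensor_labels`).
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noise-free.
#' @param seed integer seed making the noise deterministic.
#' @param noise_sd optional absolute noise standard deviation overriding the
#'   SNR-derived scale.
#' @return A `sensor_recording`: list with `data` (`n_sensors x n_samples`),
#'   `fs`, `labels`, `subject`, `task`.
#' @export
project_to_sensors <- function(src, lf, snr_db = Inf, seed = 1, noise_sd = NULL) {
  A <- lf$A
  if (ncol(A) != nrow(src$data))
    stop("lead field has ", ncol(A), " columns but recording has ",
         nrow(src$data), " sources")
  Y <- A %*% src$data
  if (is.null(noise_sd)) {
    if (is.finite(snr_db)) {
      p_sig <- mean(Y^2)
      if (p_sig == 0)
        stop("projected signal has zero power; supply noise_sd directly")
      noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
    } else noise_sd <- 0
  }
  if (noise_sd > 0)
    Y <- Y + with_local_seed(seed,
      matrix(stats::rnorm(length(Y), sd = noise_sd), nrow = nrow(Y)))
  structure(list(data = Y, fs = src$fs, labels = lf$sensor_labels,
                 subject = src$subject, task = src$task),
            class = "sensor_recording")
}

#' Generate a full synthetic sensor-space cohort
#'
#' Runs [generate_sources()] and [project_to_sensors()] for every
#' `(subject, task)` cell of the configuration. The same configuration and
#' seed always reproduce the identical cohort.
#'
#' The sensor noise level is fixed once for the whole cohort: `snr_db`
#' is interpreted against the expected sensor power of the unit-variance
#' source background under the given lead field
#' (`mean_i sum_j A_ij^2`), so the noise standard deviation is identical
#' for every subject and task. Sensor noise is an instrument property; if
#' it instead tracked each recording's realized signal power, a planted
#' task manipulation would leak into every frequency band through the
#' noise scale.
#'
#' @param config a [cohort_config()].
#' @param lf lead field used for the source-to-sensor projection.
#' @return An `eeg_cohort`: named list of `sensor_recording`s keyed
#'   `"S01.FIX"` etc., with attributes `index` (data.frame of subject/task),
#'   `truth` (per-recording planted networks after jitter) and `config`.
#' @export
generate_cohort <- function(config, lf) {
  stopifnot(inherits(config, "cohort_config"))
  recs <- list(); truth <- list()
  noise_sd <- if (is.finite(config$snr_db))
    sqrt(mean(rowSums(lf$A^2)) / 10^(config$snr_db / 10)) else 0
  idx <- expand.grid(subject = seq_len(config$n_subjects),
                     task = config$tasks, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  for (r in seq_len(nrow(idx))) {
    s <- idx$subject[r]; tk <- idx$task[r]
    gs <- generate_sources(config, s, tk)
    key <- paste0(sprintf("S%02d", s), ".", tk)
    nseed <- substream_seed(config$seed, s, 500000L + match(tk, config$tasks))
    recs[[key]] <- project_to_sensors(gs$rec, lf, config$snr_db, nseed,
                                      noise_sd = noise_sd)
    truth[[key]] <- gs$planted
  }
  structure(recs,
            index = data.frame(key = names(recs),
                               subject = sprintf("S%02d", idx$subject),
                               task = idx$task, stringsAsFactors = FALSE),
            truth = truth, config = config, class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  idx <- attr(x, "index")
  cat("eeg_cohort:", length(x), "recordings,",
      length(unique(idx$subject)), "subjects x",
      length(unique(idx$task)), "tasks\n")
  invisible(x)
}

#' Write a cohort to disk as TSV matrices with JSON sidecars
#'
#' One tab-separated file per recording (samples in rows, channels in
#' columns, header = channel labels) plus a JSON sidecar holding sampling
#' rate, labels, subject and task, and a cohort-level `manifest.json` with
#' the seed, configuration summary and planted ground truth.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- attr(cohort, "index"); config <- attr(cohort, "config")
  files <- character(0)
  for (key in names(cohort)) {
    rec <- cohort[[key]]
    base <- file.path(dir, gsub("\\.", "_", key))
    utils::write.table(t(rec$data), paste0(base, ".tsv"), sep = "\t",
                       row.names = FALSE, col.names = rec$labels,
                       quote = FALSE)
    jsonlite::write_json(list(fs = rec$fs, labels = rec$labels,
                              subject = rec$subject, task = rec$task),
                         paste0(base, ".json"), auto_unbox = TRUE)
    files <- c(files, paste0(base, ".tsv"))
  }
  manifest <- file.path(dir, "manifest.json")
  truth <- lapply(attr(cohort, "truth"), function(nets)
    lapply(nets, function(pn) list(band = pn$band,
                                   edges = unclass(pn$edges),
                                   mixing = pn$mixing)))
  jsonlite::write_json(list(seed = config$seed,
                            n_subjects = config$n_subjects,
                            tasks = config$tasks, fs = config$fs,
                            duration_s = config$duration_s,
                            snr_db = config$snr_db,
                            files = basename(files), truth = truth),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
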