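#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's settings: the synthetic cohort (or a directory of
#' recorded segments), head-model geometry and regularization, spectral
#' estimation, band definitions, and the statistical contrasts.
#'
#' @param cohort a [cohort_config()], or a directory path containing
#'   TSV+JSON recordings to ingest.
#' @param n_sensors sensor count for the head model.
#' @param geometry head geometry, see [head_geometry()].
#' @param lambda regularization scalar; `NULL` selects it by the
#'   discrepancy principle from the cohort's SNR ([choose_lambda()]).
#' @param spectral a [spectral_config()].
#' @param bands band table; defaults to the cohort's bands.
#' @param q FDR level for all comparisons.
#' @param metrics graph metrics to compute per matrix (see
#'   [summarize_graph()]).
#' @param n_random surrogate count for small-worldness (ignored unless
#'   `"swn"` is requested).
#' @param control_task label of the control condition for edge difference
#'   maps (default `"FIX"`).
#' @param output_dir directory for persisted outputs; `NULL` disables
#'   writing entirely.
#' @param persist_adjacency write one TSV per adjacency matrix (large at
#'   full scale).
#' @param keep_adjacency retain all adjacency matrices in the returned
#'   object.
#' @param seed master seed for every stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), n_sensors = 28,
                       geometry = head_geometry(), lambda = NULL,
                       spectral = spectral_config(), bands = NULL,
                       q = 0.05, metrics = c("ns", "eglob", "eloc", "cc", "L", "swn"),
                       n_random = 100, control_task = "FIX",
                       output_dir = NULL, persist_adjacency = FALSE,
                       keep_adjacency = FALSE, seed = 1) {
  if (inherits(cohort, "cohort_config") && is.null(bands)) bands <- cohort$bands
  if (is.null(bands)) bands <- default_bands()
  if (is.character(cohort) && !dir.exists(cohort))
    stop("input directory does not exist: ", cohort)
  structure(list(cohort = cohort, n_sensors = n_sensors, geometry = geometry,
                 lambda = lambda, spectral = spectral, bands = bands, q = q,
                 metrics = metrics, n_random = n_random,
                 control_task = control_task, output_dir = output_dir,
                 persist_adjacency = persist_adjacency,
                 keep_adjacency = keep_adjacency, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes, in order: cohort simulation (or ingestion), head-model and
#' inverse-kernel construction, per-recording source estimation, per-band
#' MSC adjacency matrices (one cross-spectral pass per recording, streamed
#' so memory stays flat), graph summaries, and group statistics (pairwise
#' task U tests with FDR per band and metric, per-node node-strength
#' contrasts, and task-minus-control edge difference maps). Rerunning with
#' an identical configuration reproduces all numeric outputs exactly.
#'
#' @param config a [run_config()].
#' @return A `cortexnet_run`: list with `summaries` (data.frame),
#'   `scalar_stats`, `node_stats`, `edge_maps`, `ns` (per band/task
#'   subject-by-node matrices), `lead_field`, `kernel`, `counts`,
#'   `manifest` and optionally `adjacency`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  warnings_log <- character(0)

  stage <- "cohort"
  res <- tryCatch({
    if (is.character(config$cohort)) {
      cohort <- ingest_recordings(config$cohort, config$spectral)
      ccfg <- NULL
      n_dipoles <- NULL  # resolved after the lead field is built
      snr_db <- Inf
    } else {
      ccfg <- config$cohort
      n_dipoles <- ccfg$n_sources
      snr_db <- ccfg$snr_db
      cohort <- NULL  # generated after the lead field below
    }

    stage <- "headmodel"
    if (is.null(n_dipoles)) n_dipoles <- 258L
    lf <- build_lead_field(config$n_sensors, n_dipoles, config$geometry,
                           seed = substream_seed(config$seed, 1L))
    lambda <- if (is.null(config$lambda)) choose_lambda(lf, snr_db) else config$lambda
    kernel <- compute_inverse_kernel(lf, lambda)

    if (is.null(cohort)) {
      stage <- "synthcortex"
      cohort <- generate_cohort(ccfg, lf)
    }

    stage <- "bandcoh/graphmetrics"
    idx <- attr(cohort, "index")
    bands <- config$bands
    out_dir <- config$output_dir
    if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                      showWarnings = FALSE)
    adj_dir <- if (!is.null(out_dir) && config$persist_adjacency)
      file.path(out_dir, "adjacency") else NULL
    if (!is.null(adj_dir)) dir.create(adj_dir, showWarnings = FALSE)

    n_adj <- 0L; adj_dim <- NA_integer_
    sum_rows <- list(); ns_store <- list(); mean_acc <- list(); mean_n <- list()
    kept <- if (config$keep_adjacency) list() else NULL
    files <- character(0)

    for (r in seq_len(nrow(idx))) {
      key <- idx$key[r]
      rec <- cohort[[key]]
      est <- apply_kernel(kernel, rec)
      mats <- msc_matrix(est$data, rec$fs, config$spectral, bands)
      for (bi in seq_len(nrow(bands))) {
        b <- bands$name[bi]
        W <- mats[[b]]
        n_adj <- n_adj + 1L
        adj_dim <- nrow(W)
        gs <- summarize_graph(W, n_random = config$n_random,
                              seed = substream_seed(config$seed, r, bi),
                              metrics = config$metrics)
        if (gs$disconnected)
          warnings_log <- c(warnings_log,
                            paste0("disconnected graph: ", key, " band ", b))
        sum_rows[[length(sum_rows) + 1L]] <- data.frame(
          subject = idx$subject[r], task = idx$task[r], band = b,
          eglob = gs$eglob, eloc = gs$eloc, cc = gs$cc, L = gs$L,
          swn = gs$swn, mean_ns = if (all(is.na(gs$ns))) NA else mean(gs$ns),
          stringsAsFactors = FALSE)
        if (!all(is.na(gs$ns))) {
          skey <- paste(b, idx$task[r], sep = "|")
          ns_store[[skey]] <- rbind(ns_store[[skey]], gs$ns)
        }
        mkey <- paste(b, idx$task[r], sep = "|")
        if (is.null(mean_acc[[mkey]])) {
          mean_acc[[mkey]] <- W; mean_n[[mkey]] <- 1L
        } else {
          mean_acc[[mkey]] <- mean_acc[[mkey]] + W
          mean_n[[mkey]] <- mean_n[[mkey]] + 1L
        }
        if (!is.null(adj_dir)) {
          f <- file.path(adj_dir, paste0(gsub("[|.]", "_", key), "_", b, ".tsv"))
          utils::write.table(signif(W, 8), f, sep = "\t", row.names = FALSE,
                             col.names = FALSE, quote = FALSE)
          files <- c(files, f)
        }
        if (!is.null(kept)) kept[[paste(idx$subject[r], b, idx$task[r],
                                        sep = "|")]] <- W
      }
    }
    summaries <- do.call(rbind, sum_rows)
    means <- Map(function(acc, n) acc / n, mean_acc, mean_n)

    stage <- "groupstats"
    tasks <- unique(idx$task)
    scalar_metrics <- intersect(config$metrics, c("eglob", "eloc", "cc", "L", "swn"))
    scalar_stats <- NULL
    if (length(tasks) >= 2 && length(scalar_metrics)) {
      st <- list()
      for (b in bands$name) for (m in scalar_metrics)
        st[[paste(b, m)]] <- compare_tasks(summaries, m, b, config$q)
      scalar_stats <- do.call(rbind, st)
      rownames(scalar_stats) <- NULL
    }

    node_stats <- list()
    if ("ns" %in% config$metrics && length(tasks) >= 2) {
      prs <- utils::combn(tasks, 2)
      for (b in bands$name) for (j in seq_len(ncol(prs))) {
        ta <- prs[1, j]; tb <- prs[2, j]
        ka <- paste(b, ta, sep = "|"); kb <- paste(b, tb, sep = "|")
        if (is.null(ns_store[[ka]]) || is.null(ns_store[[kb]])) next
        node_stats[[paste(b, ta, tb, sep = "|")]] <-
          compare_node_strength(ns_store[[ka]], ns_store[[kb]], ta, tb,
                                config$q)
      }
    }

    edge_maps <- list()
    ctrl <- config$control_task
    if (ctrl %in% tasks) {
      thr <- edge_threshold_defaults()
      for (b in bands$name) for (tk in setdiff(tasks, ctrl)) {
        kt <- paste(b, tk, sep = "|"); kc <- paste(b, ctrl, sep = "|")
        if (is.null(means[[kt]]) || is.null(means[[kc]])) next
        th <- if (b %in% names(thr)) thr[[b]] else 0.1
        edge_maps[[paste(b, tk, sep = "|")]] <-
          edge_difference_map(means[[kt]], means[[kc]], th)
      }
    }

    stage <- "manifest"
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "summaries.tsv")
      utils::write.table(summaries, f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, f)
      if (!is.null(scalar_stats)) {
        f <- file.path(out_dir, "stats_scalar.tsv")
        utils::write.table(scalar_stats, f, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        files <- c(files, f)
      }
      if (length(node_stats)) {
        ns_long <- do.call(rbind, lapply(names(node_stats), function(k) {
          m <- node_stats[[k]]
          data.frame(contrast_band = k, node = seq_along(m$p_raw),
                     p_raw = m$p_raw, p_fdr = m$p_fdr, reject = m$reject,
                     stringsAsFactors = FALSE)
        }))
        f <- file.path(out_dir, "node_stats.tsv")
        utils::write.table(ns_long, f, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        files <- c(files, f)
      }
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("cortexnet")),
      seed = config$seed, lambda = lambda,
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      n_recordings = nrow(idx), n_adjacency = n_adj,
      adjacency_dim = adj_dim,
      n_summary_rows = nrow(summaries),
      kernel_dim = dim(kernel$K),
      config = serialize_run_config(config),
      warnings = warnings_log,
      files = if (length(files))
        data.frame(path = files, md5 = unname(tools::md5sum(files)),
                   stringsAsFactors = FALSE) else NULL)
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    structure(list(summaries = summaries, scalar_stats = scalar_stats,
                   node_stats = node_stats, edge_maps = edge_maps,
                   ns = ns_store, mean_adjacency = means,
                   adjacency = kept, lead_field = lf, kernel = kernel,
                   counts = list(recordings = nrow(idx), adjacency = n_adj,
                                 adjacency_dim = adj_dim),
                   manifest = manifest),
              class = "cortexnet_run")
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' @export
print.cortexnet_run <- function(x, ...) {
  cat("cortexnet_run:", x$counts$recordings, "recordings ->",
      x$counts$adjacency, "adjacency matrices (",
      x$counts$adjacency_dim, "x", x$counts$adjacency_dim, ")\n")
  invisible(x)
}

# plain-list snapshot of a run_config for the manifest / JSON round trip
serialize_run_config <- function(config) {
  ch <- config$cohort
  cohort <- if (is.character(ch)) list(input_dir = ch) else {
    list(n_subjects = ch$n_subjects, tasks = ch$tasks,
         duration_s = ch$duration_s, fs = ch$fs, n_sources = ch$n_sources,
         snr_db = ch$snr_db, seed = ch$seed, jitter = ch$jitter,
         window_s = ch$window_s,
         planted = lapply(ch$planted, function(nets) lapply(nets, function(pn)
           list(band = pn$band, edges = unclass(pn$edges),
                mixing = pn$mixing))))
  }
  list(cohort = cohort, n_sensors = config$n_sensors,
       geometry = lapply(config$geometry, unname),
       lambda = config$lambda,
       spectral = unclass(config$spectral),
       bands = config$bands, q = config$q, metrics = config$metrics,
       n_random = config$n_random, control_task = config$control_task,
       persist_adjacency = config$persist_adjacency,
       keep_adjacency = config$keep_adjacency, seed = config$seed)
}

#' Write / read a run configuration as JSON
#'
#' The serialization round-trips: reading a written configuration and
#' writing it again produces byte-identical JSON.
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(serialize_run_config(config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  bands <- do.call(rbind, lapply(j$bands, function(b)
    data.frame(name = b$name, f_lo = b$f_lo, f_hi = b$f_hi,
               stringsAsFactors = FALSE)))
  cohort <- if (!is.null(j$cohort$input_dir)) j$cohort$input_dir else {
    planted <- lapply(j$cohort$planted, function(nets) lapply(nets, function(pn)
      planted_network(pn$band, matrix(unlist(pn$edges), ncol = 2),
                      pn$mixing)))
    cohort_config(n_subjects = j$cohort$n_subjects, tasks = j$cohort$tasks,
                  duration_s = j$cohort$duration_s, fs = j$cohort$fs,
                  n_sources = j$cohort$n_sources, snr_db = j$cohort$snr_db,
                  seed = j$cohort$seed, jitter = j$cohort$jitter,
                  planted = planted, bands = bands,
                  window_s = j$cohort$window_s)
  }
  geometry <- j$geometry
  geometry$n_terms <- as.integer(geometry$n_terms)
  spec <- spectral_config(j$spectral$window_s, j$spectral$overlap,
                          j$spectral$taper,
                          if (is.null(j$spectral$nfft)) NULL else j$spectral$nfft,
                          j$spectral$min_segments)
  run_config(cohort = cohort, n_sensors = j$n_sensors, geometry = geometry,
             lambda = j$lambda, spectral = spec, bands = bands, q = j$q,
             metrics = j$metrics, n_random = j$n_random,
             control_task = j$control_task,
             persist_adjacency = isTRUE(j$persist_adjacency),
             keep_adjacency = isTRUE(j$keep_adjacency), seed = j$seed)
}

#' Ingest recorded EEG segments from a directory
#'
#' Reads every `*.tsv` matrix (samples x channels, header = labels) with
#' its `.json` sidecar (fields `fs`, `labels`, `subject`, `task`) and
#' validates it: channel labels must belong to the 28-channel 10/10 montage
#' ([eeg_1010_labels()]), all recordings must share one sampling rate, and
#' each record must span the spectral minimum segment count. Invalid
#' recordings are rejected with reasons.
#'
#' @param path directory of TSV+JSON recordings.
#' @param cfg a [spectral_config()] defining the minimum record length.
#' @return An `eeg_cohort` of validated `sensor_recording`s.
#' @export
ingest_recordings <- function(path, cfg = spectral_config()) {
  tsvs <- sort(list.files(path, "\\.tsv$", full.names = TRUE))
  tsvs <- tsvs[!grepl("manifest", basename(tsvs))]
  if (!length(tsvs)) stop("no .tsv recordings found in ", path)
  valid <- eeg_1010_labels()
  recs <- list(); idx_rows <- list()
  for (f in tsvs) {
    sidecar <- sub("\\.tsv$", ".json", f)
    if (!file.exists(sidecar)) stop("missing JSON sidecar for ", basename(f))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    m <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
    labels <- colnames(m)
    bad <- setdiff(labels, valid)
    if (length(bad))
      stop("recording ", basename(f), " has unknown channel label(s): ",
           paste(bad, collapse = ", "))
    fs <- meta$fs
    n <- nrow(m)
    lay <- tryCatch(welch_layout(n, fs, cfg), error = function(e)
      stop("recording ", basename(f), " rejected: ", conditionMessage(e),
           call. = FALSE))
    rec <- structure(list(data = t(as.matrix(m)), fs = fs, labels = labels,
                          subject = meta$subject, task = meta$task),
                     class = "sensor_recording")
    key <- paste0(meta$subject, ".", meta$task)
    recs[[key]] <- rec
    idx_rows[[key]] <- data.frame(key = key, subject = meta$subject,
                                  task = meta$task, stringsAsFactors = FALSE)
  }
  fss <- unique(vapply(recs, `[[`, 0, "fs"))
  if (length(fss) > 1)
    stop("sampling-rate mismatch across recordings: ",
         paste(fss, collapse = ", "))
  structure(recs, index = do.call(rbind, idx_rows), truth = NULL,
            config = NULL, class = "eeg_cohort")
}
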