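#' Spectral estimation settings for Welch coherence
#'
#' @param window_s window length in seconds (default 1 s: with a 500 Hz
#'   sampling rate this gives 1 Hz bin spacing, enough to resolve the delta
#'   band, and 19 segments per 10 s record at 50 percent overlap).
#' @param overlap fractional segment overlap in `[0, 1)`.
#' @param taper taper name; only `"hann"` is implemented.
#' @param nfft FFT length in samples; defaults to the window length.
#' @param min_segments minimum admissible number of Welch segments.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 1, overlap = 0.5, taper = "hann",
                            nfft = NULL, min_segments = 8) {
  stopifnot(window_s > 0, overlap >= 0, overlap < 1)
  if (taper != "hann") stop("only the hann taper is implemented")
  structure(list(window_s = window_s, overlap = overlap, taper = taper,
                 nfft = nfft, min_segments = min_segments),
            class = "spectral_config")
}

# segment layout for a record of n samples; errors if too short
welch_layout <- function(n, fs, cfg) {
  L <- as.integer(round(cfg$window_s * fs))
  if (L < 8) stop("window too short: ", L, " samples")
  step <- max(1L, as.integer(round(L * (1 - cfg$overlap))))
  if (n < L) stop("record shorter than one Welch window")
  starts <- seq.int(1L, n - L + 1L, by = step)
  K <- length(starts)
  if (K < cfg$min_segments) {
    need <- L + (cfg$min_segments - 1) * step
    stop("only ", K, " Welch segments available; at least ",
         cfg$min_segments, " required (record length >= ", need,
         " samples, i.e. ", signif(need / fs, 4), " s)")
  }
  nfft <- if (is.null(cfg$nfft)) L else as.integer(cfg$nfft)
  if (nfft < L) stop("nfft must be at least the window length")
  list(L = L, step = step, starts = starts, K = K, nfft = nfft)
}

# periodic Hann window
hann_window <- function(L) 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / L))

# tapered segment FFTs for all channels at once.
# Returns list(F = complex matrix [n_bins x (n_ch * K)] with channels
# varying fastest, freqs, n_ch, K).
welch_fft <- function(data, fs, cfg) {
  data <- as.matrix(data)
  n_ch <- nrow(data); n <- ncol(data)
  lay <- welch_layout(n, fs, cfg)
  win <- hann_window(lay$L)
  seg <- matrix(0, lay$nfft, n_ch * lay$K)
  for (k in seq_len(lay$K)) {
    idx <- lay$starts[k]:(lay$starts[k] + lay$L - 1L)
    cols <- (k - 1L) * n_ch + seq_len(n_ch)
    seg[seq_len(lay$L), cols] <- t(data[, idx, drop = FALSE]) * win
  }
  Fm <- stats::mvfft(seg)
  n_bins <- lay$nfft %/% 2L + 1L
  list(F = Fm[seq_len(n_bins), , drop = FALSE],
       freqs = (seq_len(n_bins) - 1) * fs / lay$nfft,
       n_ch = n_ch, K = lay$K)
}

# indices of frequency bins whose center lies in [f_lo, f_hi)
band_bins <- function(freqs, f_lo, f_hi) which(freqs >= f_lo & freqs < f_hi)

#' Magnitude-squared coherence of one signal pair within a band
#'
#' Welch-averaged cross- and auto-spectra give
#' `MSC(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))`, which is then averaged over
#' the frequency bins whose centers fall in `[f_lo, f_hi)`. The estimate
#' lies in `[0, 1]`; for independent signals its expectation is
#' approximately `1/K` for `K` averaged segments (the estimator's bias
#' floor), and it is invariant to scaling or sign flips of either input.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate in Hz.
#' @param cfg a [spectral_config()].
#' @param band one-row band table (name, f_lo, f_hi) or a list with
#'   `f_lo`/`f_hi`.
#' @return Scalar MSC in `[0, 1]`.
#' @export
msc_pair <- function(x, y, fs, cfg = spectral_config(), band) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  lay <- welch_layout(length(x), fs, cfg)
  win <- hann_window(lay$L)
  n_bins <- lay$nfft %/% 2L + 1L
  pxx <- pyy <- numeric(n_bins); pxy <- complex(n_bins)
  for (k in seq_len(lay$K)) {
    idx <- lay$starts[k]:(lay$starts[k] + lay$L - 1L)
    fx <- stats::fft(c(x[idx] * win, numeric(lay$nfft - lay$L)))[seq_len(n_bins)]
    fy <- stats::fft(c(y[idx] * win, numeric(lay$nfft - lay$L)))[seq_len(n_bins)]
    pxx <- pxx + Mod(fx)^2
    pyy <- pyy + Mod(fy)^2
    pxy <- pxy + fx * Conj(fy)
  }
  freqs <- (seq_len(n_bins) - 1) * fs / lay$nfft
  bins <- band_bins(freqs, band$f_lo, band$f_hi)
  if (!length(bins)) stop("no frequency bins fall inside the band")
  denom <- pxx[bins] * pyy[bins]
  msc <- ifelse(denom > 0, Mod(pxy[bins])^2 / denom, 0)
  mean(msc)
}

#' Per-band MSC adjacency matrices from a multichannel recording
#'
#' One cross-spectral-density pass over the Welch segment FFTs yields, for
#' every frequency bin of interest, the full channels-by-channels MSC
#' matrix; per-bin matrices are averaged within each band. Results are
#' identical (to numerical precision) to calling [msc_pair()] on every
#' pair. Each returned matrix is symmetric with entries in `[0, 1]` and a
#' zero diagonal, and no thresholding is applied.
#'
#' @param data numeric matrix, channels x samples (or a recording object
#'   with a `data` field).
#' @param fs sampling rate in Hz.
#' @param cfg a [spectral_config()].
#' @param bands band table with columns `name`, `f_lo`, `f_hi`.
#' @return Named list of `n_ch x n_ch` matrices, one per band.
#' @export
msc_matrix <- function(data, fs, cfg = spectral_config(),
                       bands = default_bands()) {
  if (is.list(data) && !is.null(data$data)) data <- data$data
  wf <- welch_fft(data, fs, cfg)
  n_ch <- wf$n_ch
  out <- lapply(seq_len(nrow(bands)), function(bi) {
    bins <- band_bins(wf$freqs, bands$f_lo[bi], bands$f_hi[bi])
    if (!length(bins))
      stop("no frequency bins fall inside band ", bands$name[bi])
    acc <- matrix(0, n_ch, n_ch)
    for (f in bins) {
      Xf <- matrix(wf$F[f, ], n_ch, wf$K)
      S <- Xf %*% Conj(t(Xf))
      p <- Re(diag(S))
      denom <- outer(p, p)
      m <- Mod(S)^2
      m <- ifelse(denom > 0, m / denom, 0)
      acc <- acc + m
    }
    W <- acc / length(bins)
    W <- (W + t(W)) / 2
    W[W > 1] <- 1
    diag(W) <- 0
    W
  })
  names(out) <- bands$name
  out
}

#' MSC adjacency matrix for one band
#'
#' @param src a `source_recording` (or any recording with `data` and `fs`).
#' @param fs sampling rate; defaults to `src$fs`.
#' @param cfg a [spectral_config()].
#' @param band one-row band table.
#' @return Matrix with attributes `band`, `subject`, `task`.
#' @export
adjacency <- function(src, fs = src$fs, cfg = spectral_config(), band) {
  W <- msc_matrix(src$data, fs, cfg, band)[[1]]
  attr(W, "band") <- band$name
  attr(W, "subject") <- src$subject
  attr(W, "task") <- src$task
  W
}

#' Cohort-wide adjacency matrices
#'
#' Estimates source activity for every recording and computes per-band MSC
#' adjacency matrices, reusing one cross-spectral pass per recording across
#' all bands. A complete cohort of `n_subjects` subjects, `n_tasks` tasks
#' and `n_bands` bands yields exactly `n_subjects * n_bands * n_tasks`
#' matrices.
#'
#' @param cohort an `eeg_cohort` (sensor space).
#' @param kernel an `inverse_kernel`; `NULL` computes coherence directly on
#'   the stored recordings (e.g. when they are already source estimates).
#' @param cfg a [spectral_config()].
#' @param bands band table.
#' @return Named list of matrices keyed `"subject|band|task"`, with an
#'   `index` attribute data.frame.
#' @export
cohort_adjacency <- function(cohort, kernel = NULL, cfg = spectral_config(),
                             bands = default_bands()) {
  idx <- attr(cohort, "index")
  subjects <- unique(idx$subject); tasks <- unique(idx$task)
  grid <- expand.grid(subject = subjects, task = tasks,
                      stringsAsFactors = FALSE)
  have <- paste(idx$subject, idx$task)
  gaps <- setdiff(paste(grid$subject, grid$task), have)
  if (length(gaps))
    stop("missing (subject, task) cells: ", paste(gaps, collapse = "; "))
  out <- list()
  rows <- list()
  for (key in names(cohort)) {
    rec <- cohort[[key]]
    est <- if (is.null(kernel)) rec else apply_kernel(kernel, rec)
    mats <- msc_matrix(est$data, rec$fs, cfg, bands)
    for (b in names(mats)) {
      okey <- paste(rec$subject, b, rec$task, sep = "|")
      out[[okey]] <- mats[[b]]
      rows[[okey]] <- data.frame(subject = rec$subject, band = b,
                                 task = rec$task, stringsAsFactors = FALSE)
    }
  }
  structure(out, index = do.call(rbind, rows), class = "adjacency_set")
}
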