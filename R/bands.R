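#' Canonical EEG frequency bands
#'
#' Returns the six-band partition used throughout the pipeline. Each band is
#' a half-open interval `[f_lo, f_hi)` in Hz; the six bands are disjoint.
#' Band edges follow the conventional splits (delta 1-4, theta 4-8,
#' alpha1 8-10, alpha2 10-13, beta 13-30, gamma 30-45 Hz) and are fully
#' configurable via [band_spec()].
#'
#' @param names optional character vector to subset/reorder the defaults.
#' @return A data.frame with columns `name`, `f_lo`, `f_hi`.
#' @export
#' @examples
#' default_bands()
#' default_bands(c("delta", "gamma"))
default_bands <- function(names = NULL) {
  b <- data.frame(
    name = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
    f_lo = c(1, 4, 8, 10, 13, 30),
    f_hi = c(4, 8, 10, 13, 30, 45),
    stringsAsFactors = FALSE
  )
  if (is.null(names)) return(b)
  missing <- setdiff(names, b$name)
  if (length(missing))
    stop("unknown band name(s): ", paste(missing, collapse = ", "))
  b[match(names, b$name), , drop = FALSE]
}

#' Construct a band specification table
#'
#' @param name character vector of band names.
#' @param f_lo,f_hi numeric vectors of lower/upper edges in Hz; each band is
#'   the half-open interval `[f_lo, f_hi)`.
#' @param fs optional sampling rate; if given, `f_hi <= fs/2` is enforced.
#' @return A data.frame with columns `name`, `f_lo`, `f_hi`.
#' @export
band_spec <- function(name, f_lo, f_hi, fs = NULL) {
  stopifnot(length(name) == length(f_lo), length(f_lo) == length(f_hi))
  if (any(f_lo <= 0) || any(f_hi <= f_lo))
    stop("bands require 0 < f_lo < f_hi")
  if (!is.null(fs) && any(f_hi > fs / 2))
    stop("f_hi exceeds the Nyquist frequency fs/2 = ", fs / 2)
  b <- data.frame(name = as.character(name), f_lo = as.numeric(f_lo),
                  f_hi = as.numeric(f_hi), stringsAsFactors = FALSE)
  o <- order(b$f_lo)
  bo <- b[o, ]
  if (any(bo$f_hi[-nrow(bo)] > bo$f_lo[-1] + 1e-12))
    stop("bands must be disjoint")
  b
}

#' Per-band display thresholds for edge difference maps
#'
#' Defaults used when rendering task-minus-control connection differences on
#' complete weighted graphs: 0.10 for the four low-frequency bands and 0.05
#' for beta and gamma.
#'
#' @return Named numeric vector of thresholds keyed by band name.
#' @export
edge_threshold_defaults <- function() {
  c(delta = 0.10, theta = 0.10, alpha1 = 0.10, alpha2 = 0.10,
    beta = 0.05, gamma = 0.05)
}
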