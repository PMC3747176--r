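#' The 28-channel 10/10 sensor montage
#'
#' Symmetric 28-label subset of the extended international 10/10 system used
#' for validation of ingested recordings and for the spherical sensor
#' layout: nine electrode sites per hemisphere, six midline sites, and the
#' temporo-parietal / parieto-occipital pairs TP7/TP8, PO7/PO8.
#'
#' @return Character vector of 28 channel labels.
#' @export
eeg_1010_labels <- function() {
  montage_1010()$label
}

# montage table: inclination theta from the vertex and azimuth measured
# from the nasion direction, positive toward the right ear (degrees)
montage_1010 <- function() {
  m <- rbind(
    c("FP1", 72, -18), c("FP2", 72, 18),
    c("F7",  72, -54), c("F8",  72, 54),
    c("F3",  52, -39), c("F4",  52, 39),  c("Fz",  36, 0),
    c("FT7", 72, -72), c("FT8", 72, 72),
    c("FC3", 32, -45), c("FC4", 32, 45),  c("FCz", 18, 0),
    c("C3",  36, -90), c("C4",  36, 90),  c("Cz",  0,  0),
    c("TP7", 72, -108), c("TP8", 72, 108),
    c("CP3", 32, -135), c("CP4", 32, 135), c("CPz", 18, 180),
    c("P3",  52, -141), c("P4",  52, 141), c("Pz",  36, 180),
    c("PO7", 72, -144), c("PO8", 72, 144),
    c("O1",  72, -162), c("O2",  72, 162), c("Oz",  72, 180))
  data.frame(label = m[, 1], theta = as.numeric(m[, 2]),
             azimuth = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

# unit direction vectors; front = +y, right = +x, vertex = +z
angles_to_xyz <- function(theta_deg, az_deg) {
  th <- theta_deg * pi / 180; az <- az_deg * pi / 180
  cbind(x = sin(th) * sin(az), y = sin(th) * cos(az), z = cos(th))
}

# near-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Default three-shell spherical head geometry
#'
#' Shell radii are expressed as fractions of the scalp radius (brain 0.87,
#' skull 0.92, scalp 1.0) with conductivities 0.33, 0.0042, 0.33 S/m — the
#' conventional 1:1/80:1 scalp:skull:scalp ratio. Dipoles sit on an inner
#' sphere at radius 0.78 with a small seeded placement jitter.
#'
#' @return Named list of geometry parameters.
#' @export
head_geometry <- function() {
  list(radii = c(brain = 0.87, skull = 0.92, scalp = 1.0),
       sigmas = c(brain = 0.33, skull = 0.0042, scalp = 0.33),
       dipole_radius = 0.78, dipole_jitter = 0.015, n_terms = 80L)
}

# per-degree transfer coefficient of the three-shell model: potential
# coefficient on the scalp surface for a unit source term S r^-(n+1) in the
# innermost region. Solves the 5x5 boundary-condition system per degree.
three_shell_transfer <- function(n_terms, radii, sigmas) {
  r1 <- radii[1]; r2 <- radii[2]; r3 <- radii[3]
  s1 <- sigmas[1]; s2 <- sigmas[2]; s3 <- sigmas[3]
  if (any(diff(radii) <= 0)) stop("degenerate geometry: shells must satisfy r1 < r2 < r3")
  vapply(seq_len(n_terms), function(n) {
    # unknowns: A1, A2, B2, A3, B3
    M <- rbind(
      c(r1^n, -r1^n, -r1^(-n - 1), 0, 0),
      c(s1 * n * r1^(n - 1), -s2 * n * r1^(n - 1), s2 * (n + 1) * r1^(-n - 2), 0, 0),
      c(0, r2^n, r2^(-n - 1), -r2^n, -r2^(-n - 1)),
      c(0, s2 * n * r2^(n - 1), -s2 * (n + 1) * r2^(-n - 2),
        -s3 * n * r2^(n - 1), s3 * (n + 1) * r2^(-n - 2)),
      c(0, 0, 0, n * r3^(n - 1), -(n + 1) * r3^(-n - 2)))
    rhs <- c(-r1^(-n - 1), s1 * (n + 1) * r1^(-n - 2), 0, 0, 0)
    co <- solve(M, rhs)
    co[4] * r3^n + co[5] * r3^(-n - 1)
  }, numeric(1))
}

# Legendre polynomials P_1..P_nmax evaluated at every element of matrix x,
# weighted-summed with coefficients w_n(b) per dipole column
legendre_series <- function(x, wmat) {
  # x: sensors x dipoles matrix of cos(gamma); wmat: n_terms x dipoles
  n_terms <- nrow(wmat)
  p_prev <- matrix(1, nrow(x), ncol(x))   # P_0
  p_cur <- x                              # P_1
  out <- p_cur * matrix(wmat[1, ], nrow(x), ncol(x), byrow = TRUE)
  for (n in 1:(n_terms - 1)) {
    p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
    out <- out + p_next * matrix(wmat[n + 1, ], nrow(x), ncol(x), byrow = TRUE)
    p_prev <- p_cur; p_cur <- p_next
  }
  out
}

#' Build a spherical three-shell lead field
#'
#' Places sensors on the scalp sphere (the 28-channel 10/10 montage when
#' `n_sensors <= 28`, otherwise a Fibonacci layout on the upper hemisphere)
#' and radially oriented dipoles on an inner sphere (Fibonacci lattice with
#' seeded jitter), then evaluates the analytic three-concentric-spheres
#' forward solution per sensor-dipole pair. Dipole orientation is fixed
#' radial, giving one scalar time series per dipole.
#'
#' @param n_sensors number of sensors (>= 2).
#' @param n_dipoles number of cortical dipoles.
#' @param geometry list as returned by [head_geometry()].
#' @param seed integer seed for the dipole placement jitter.
#' @return A `lead_field`: list with matrix `A` (`n_sensors x n_dipoles`),
#'   `sensor_labels`, `sensor_positions`, `dipole_positions`, `geometry`.
#' @export
build_lead_field <- function(n_sensors = 28, n_dipoles = 258,
                             geometry = head_geometry(), seed = 1) {
  stopifnot(n_sensors >= 2, n_dipoles >= 1)
  radii <- unname(geometry$radii); sigmas <- unname(geometry$sigmas)
  mont <- montage_1010()
  if (n_sensors <= nrow(mont)) {
    mont <- mont[seq_len(n_sensors), ]
    sens_dir <- angles_to_xyz(mont$theta, mont$azimuth)
    labels <- mont$label
  } else {
    pts <- fibonacci_sphere(2 * n_sensors)
    pts <- pts[pts[, 3] > 0, , drop = FALSE][seq_len(n_sensors), ]
    sens_dir <- pts / sqrt(rowSums(pts^2))
    labels <- sprintf("E%03d", seq_len(n_sensors))
  }
  sens_pos <- sens_dir * radii[3]

  dip_dir <- fibonacci_sphere(n_dipoles)
  b <- with_local_seed(seed, {
    jit <- matrix(stats::rnorm(3 * n_dipoles, sd = geometry$dipole_jitter),
                  ncol = 3)
    d <- dip_dir + jit
    d / sqrt(rowSums(d^2))
  })
  dip_r <- geometry$dipole_radius
  dip_pos <- b * dip_r

  tn <- three_shell_transfer(geometry$n_terms, radii, sigmas)
  # source coefficient per degree and dipole: n * b^(n-1) / (4 pi sigma1)
  nn <- seq_len(geometry$n_terms)
  wmat <- outer(nn, rep(dip_r, n_dipoles),
                function(n, r) n * r^(n - 1)) * tn / (4 * pi * sigmas[1])
  cosg <- sens_dir %*% t(b)
  cosg[cosg > 1] <- 1; cosg[cosg < -1] <- -1
  A <- legendre_series(cosg, wmat)
  if (any(colSums(A^2) == 0)) stop("lead field has an all-zero column")
  structure(list(A = A, sensor_labels = labels, sensor_positions = sens_pos,
                 dipole_positions = dip_pos, geometry = geometry, seed = seed),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat("lead_field:", nrow(x$A), "sensors x", ncol(x$A), "dipoles",
      "(three-shell spherical model)\n")
  invisible(x)
}

#' Column-norm-normalized regularized inverse kernel
#'
#' Computes the weighted minimum-norm solution of
#' `min ||y - A x||^2 + lambda^2 ||W x||^2` with depth weighting
#' `W = diag(||a_j||)` over lead-field columns `a_j` — equivalently
#' `K = C A' (A C A' + lambda^2 I)^-1` with `C = diag(1 / ||a_j||^2)`. The
#' column-norm normalization counteracts the superficial-source bias of the
#' plain minimum-norm estimate.
#'
#' @param lf a `lead_field`.
#' @param lambda regularization scalar `>= 0`.
#' @return An `inverse_kernel`: list with matrix `K`
#'   (`n_dipoles x n_sensors`), `lambda`, and the sensor labels/column norms
#'   needed to apply it.
#' @export
compute_inverse_kernel <- function(lf, lambda) {
  stopifnot(lambda >= 0)
  A <- lf$A
  cn2 <- colSums(A^2)
  AC <- sweep(A, 2, cn2, "/")            # A C
  M <- AC %*% t(A) + diag(lambda^2, nrow(A))
  if (rcond(M) < 1e-12) {
    r <- qr(A)$rank
    stop("singular sensor-space system at lambda = ", lambda,
         ": lead field rank ", r, " < ", nrow(A), " sensors")
  }
  K <- t(AC) %*% solve(M)
  structure(list(K = K, lambda = lambda, sensor_labels = lf$sensor_labels,
                 column_norms = sqrt(cn2)),
            class = "inverse_kernel")
}

#' Regularization constant from the discrepancy principle
#'
#' Scales `lambda^2` to the expected noise-to-signal power ratio at the
#' sensors: `lambda^2 = trace(A C A') / (n_sensors * 10^(snr_db/10))`, the
#' standard whitened-operator heuristic. With `snr_db = Inf` this returns 0.
#'
#' @param lf a `lead_field`.
#' @param snr_db assumed sensor signal-to-noise ratio in dB.
#' @return Non-negative scalar lambda.
#' @export
choose_lambda <- function(lf, snr_db) {
  if (!is.finite(snr_db)) return(0)
  A <- lf$A
  cn2 <- colSums(A^2)
  tr <- sum(rowSums(sweep(A, 2, cn2, "/") * A))   # trace(A C A')
  sqrt(tr / (nrow(A) * 10^(snr_db / 10)))
}

#' Estimate cortical source activity from sensor recordings
#'
#' Applies the inverse kernel to a sensor recording, reconciling channel
#' order by label. The sampling rate is preserved and the estimate is
#' linear in the sensor data.
#'
#' @param kernel an `inverse_kernel`.
#' @param rec a `sensor_recording`.
#' @return A `source_recording` with `n_dipoles` rows.
#' @export
apply_kernel <- function(kernel, rec) {
  perm <- match(kernel$sensor_labels, rec$labels)
  if (anyNA(perm))
    stop("sensor recording is missing channel(s): ",
         paste(kernel$sensor_labels[is.na(perm)], collapse = ", "))
  X <- kernel$K %*% rec$data[perm, , drop = FALSE]
  structure(list(data = X, fs = rec$fs,
                 source_ids = sprintf("src%03d", seq_len(nrow(X))),
                 subject = rec$subject, task = rec$task),
            class = "source_recording")
}
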