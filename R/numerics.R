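# Symplectic stage coefficients and fourth-order staggered stencils.

#' Stage coefficients for split-operator time integration
#'
#' A symplectic split-step integrator advances the electric field by
#' `c[l] * dt` and the magnetic field by `d[l] * dt` in stage `l` of each time
#' step. The weights must each sum to one; symmetric (even-order) compositions
#' are palindromic in `c` and satisfy `d[l] == d[m - l]` with `d[m] == 0`.
#'
#' @param c Numeric vector of electric-update weights (dimensionless).
#' @param d Numeric vector of magnetic-update weights (dimensionless).
#' @param p Nominal order of accuracy (positive integer).
#' @param tol Tolerance for the sum and symmetry checks.
#'
#' @details First-order one-stage splits (e.g. `c = 1`, `d = 1`) are accepted:
#' the palindromic symmetry relations only characterise symmetric compositions,
#' so they are enforced for `p >= 2` only.
#'
#' @return An object of class `stage_coefficients` with fields `c`, `d`,
#'   `m` (stage count) and `p`.
#' @seealso [yoshida_coefficients()], [leapfrog_coefficients()]
#' @export
#' @examples
#' load_stage_coefficients(c(0.5, 0.5), c(1, 0), p = 2)
load_stage_coefficients <- function(c, d, p, tol = 1e-12) {
  c <- as.numeric(c)
  d <- as.numeric(d)
  if (length(c) != length(d)) {
    stop("stage coefficient vectors `c` and `d` must have equal length")
  }
  if (!all(is.finite(c)) || !all(is.finite(d))) {
    stop("stage coefficients must be finite")
  }
  m <- length(c)
  if (length(p) != 1L || !is.finite(p) || p < 1 || p != round(p)) {
    stop("`p` must be a positive integer")
  }
  if (abs(sum(c) - 1) > tol) {
    stop(sprintf("sum(c) = %.15g differs from 1 beyond tolerance", sum(c)))
  }
  if (abs(sum(d) - 1) > tol) {
    stop(sprintf("sum(d) = %.15g differs from 1 beyond tolerance", sum(d)))
  }
  if (p >= 2) {
    if (max(abs(c - rev(c))) > tol) {
      stop("`c` is not palindromic: c[l] must equal c[m + 1 - l]")
    }
    if (abs(d[m]) > tol) {
      stop("`d[m]` must be 0 for a symmetric composition")
    }
    if (m > 1 && max(abs(d[seq_len(m - 1)] - d[rev(seq_len(m - 1))])) > tol) {
      stop("`d` violates the symmetry relation d[l] == d[m - l]")
    }
  }
  structure(
    list(c = c, d = d, m = m, p = as.integer(p)),
    class = "stage_coefficients"
  )
}

#' @export
print.stage_coefficients <- function(x, ...) {
  cat(sprintf("<stage_coefficients> m = %d stages, nominal order p = %d\n",
              x$m, x$p))
  cat("  c:", format(x$c, digits = 10), "\n")
  cat("  d:", format(x$d, digits = 10), "\n")
  invisible(x)
}

#' Fourth-order Yoshida composition coefficients
#'
#' Closed-form triple-jump construction: `w1 = 1 / (2 - 2^(1/3))`,
#' `w0 = 1 - 2 * w1`. Concatenating the three second-order split half-steps and
#' merging adjacent same-operator factors gives the four-stage set
#' `c = (w1/2, (w1 + w0)/2, (w0 + w1)/2, w1/2)`, `d = (w1, w0, w1, 0)`.
#'
#' @return A [stage_coefficients][load_stage_coefficients] object with
#'   `m = 4`, `p = 4`.
#' @export
#' @examples
#' yoshida_coefficients()
yoshida_coefficients <- function() {
  w1 <- 1 / (2 - 2^(1 / 3))
  w0 <- 1 - 2 * w1
  load_stage_coefficients(
    c = c(w1 / 2, (w1 + w0) / 2, (w0 + w1) / 2, w1 / 2),
    d = c(w1, w0, w1, 0),
    p = 4
  )
}

#' Second-order Strang-split (leapfrog) coefficients
#'
#' @return A [stage_coefficients][load_stage_coefficients] object with
#'   `m = 2`, `p = 2`.
#' @export
leapfrog_coefficients <- function() {
  load_stage_coefficients(c = c(0.5, 0.5), d = c(1, 0), p = 2)
}

#' Stability interval of a staged split-step integrator
#'
#' For a single Fourier mode the staged update reduces to a product of 2x2
#' shears in (E, H); the composition is stable while the one-step trace stays
#' within \[-2, 2\]. This returns the largest `x` such that the map is stable
#' for all `x' <= x`, where `x = c0 * dt * |g(kappa)| / delta` combines the
#' time step with the spatial-stencil symbol.
#'
#' @param coeffs A [stage_coefficients][load_stage_coefficients] object.
#' @param x_max Upper bound of the scan.
#' @param n_scan Number of scan points.
#' @return Largest stable `x` (numeric scalar).
#' @export
#' @examples
#' stage_stability_limit(leapfrog_coefficients()) # 2 for leapfrog
stage_stability_limit <- function(coeffs, x_max = 4, n_scan = 4000L) {
  stopifnot(inherits(coeffs, "stage_coefficients"))
  xs <- seq(x_max / n_scan, x_max, length.out = n_scan)
  tr <- vapply(xs, function(x) {
    M <- diag(2)
    for (l in seq_len(coeffs$m)) {
      # E shear then H shear: E' = E + c x H ; H' = H - d x E'
      M <- matrix(c(1, -coeffs$d[l] * x, 0, 1), 2, 2) %*%
        matrix(c(1, 0, coeffs$c[l] * x, 1), 2, 2) %*% M
    }
    M[1, 1] + M[2, 2]
  }, numeric(1))
  bad <- which(abs(tr) > 2 + 1e-9)
  if (length(bad) == 0L) return(x_max)
  if (bad[1] == 1L) return(0)
  xs[bad[1] - 1L]
}

#' Fourth-order staggered difference coefficients
#'
#' The unique fourth-order two-pair stencil on the staggered (Yee) lattice,
#' from Taylor expansion about the midpoint: near-neighbour weight
#' `a1 = 9/8` and far-neighbour weight `a2 = -1/24`.
#'
#' @return Named list with `a1` and `a2`.
#' @export
stencil_coefficients <- function() {
  list(a1 = 9 / 8, a2 = -1 / 24)
}

# Spatial symbol magnitude: max over kappa of |2 (a1 sin(kappa/2) + a2 sin(3 kappa/2))|.
# Equals 7/3 for the fourth-order pair and 2 for the two-point stencil.
stencil_symbol_max <- function(a1 = 9 / 8, a2 = -1 / 24) {
  kap <- seq(0, pi, length.out = 2049L)
  max(abs(2 * (a1 * sin(kap / 2) + a2 * sin(3 * kap / 2))))
}

#' Courant limit of a scheme
#'
#' Largest stable Courant number `S = c0 * dt / delta` for a staged scheme
#' with the given stage coefficients and spatial stencil, in `dim` space
#' dimensions: `S_max = x_max / (g_max * sqrt(dim))` with `x_max` the
#' integrator's stability interval and `g_max` the stencil symbol maximum.
#'
#' @param coeffs Stage coefficients.
#' @param dim Spatial dimensionality (1 or 2).
#' @param a1,a2 Staggered-stencil weights (default fourth order).
#' @return Maximum stable Courant number (scalar).
#' @export
#' @examples
#' cfl_limit(yoshida_coefficients(), dim = 1)
cfl_limit <- function(coeffs, dim = 1L, a1 = 9 / 8, a2 = -1 / 24) {
  stopifnot(dim %in% c(1L, 2L))
  stage_stability_limit(coeffs) / (stencil_symbol_max(a1, a2) * sqrt(dim))
}

#' Fourth-order staggered first derivative
#'
#' Differentiates samples given at nodes `x_i = (i - 1) * spacing`, returning
#' the derivative at the staggered midpoints `x_{i + 1/2}`. Interior midpoints
#' use the fourth-order two-pair stencil
#' `(a1 (f_{i+1/2+1/2} - f_{i}) + a2 (f_{i+2} - f_{i-1})) / spacing` with
#' `a1 = 9/8`, `a2 = -1/24`; the first and last midpoint, where the wide
#' stencil does not fit, fall back to the centred second-order difference.
#'
#' @param samples Numeric vector of length >= 4.
#' @param spacing Grid spacing (m), > 0.
#' @return Numeric vector of length `length(samples) - 1`: derivative at the
#'   staggered midpoints.
#' @export
#' @examples
#' x <- 0:9
#' staggered_diff4(x^3, 1) # exact 3 x^2 at interior midpoints
staggered_diff4 <- function(samples, spacing) {
  n <- length(samples)
  if (n < 4L) stop("`samples` must have length >= 4")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("`spacing` must be a positive scalar")
  }
  a <- stencil_coefficients()
  out <- numeric(n - 1L)
  i <- 2:(n - 2L) # midpoints with full stencil support
  out[i] <- (a$a1 * (samples[i + 1L] - samples[i]) +
               a$a2 * (samples[i + 2L] - samples[i - 1L])) / spacing
  out[1L] <- (samples[2L] - samples[1L]) / spacing
  out[n - 1L] <- (samples[n] - samples[n - 1L]) / spacing
  out
}

#' Empirical temporal order of a staged integrator
#'
#' Runs a lossless one-dimensional PEC-cavity standing mode at a fixed fine
#' spatial grid and a sequence of halved time steps, measuring the L2 error of
#' the electric field against the semi-discrete exact solution (the standing
#' mode oscillating at the spatial-stencil-modified frequency, so the measured
#' error is purely temporal). The comparison time is a generic fraction of the
#' mode period: at a full period the field sits at a cosine extremum, where
#' phase error enters only quadratically and the fitted order is inflated.
#' Fits the slope of `log2(error)` against refinement level.
#'
#' @param coeffs Stage coefficients to test.
#' @param levels Number of refinement levels (>= 3).
#' @param n_cells Cavity size in cells.
#' @param mode Standing-mode index.
#' @return Fitted temporal order (numeric scalar).
#' @export
#' @examples
#' \donttest{
#' empirical_order(leapfrog_coefficients(), levels = 4) # ~ 2
#' }
empirical_order <- function(coeffs, levels, n_cells = 48L, mode = 2L) {
  stopifnot(inherits(coeffs, "stage_coefficients"))
  if (levels < 3L) stop("`levels` must be >= 3")
  delta <- 1
  L <- n_cells * delta
  k <- mode * pi / L
  a <- stencil_coefficients()
  k_mod <- (2 / delta) * (a$a1 * sin(k * delta / 2) + a$a2 * sin(3 * k * delta / 2))
  omega <- .c0 * k_mod
  t_final <- 0.37 * 2 * pi / omega # generic phase, away from extrema and nodes
  s_lim <- cfl_limit(coeffs, dim = 1L)
  steps0 <- ceiling(t_final / (0.8 * s_lim * delta / .c0))

  errs <- vapply(seq_len(levels), function(lev) {
    steps <- steps0 * 2^(lev - 1L)
    dt <- t_final / steps
    st <- init_state_1d(n_cells, delta, dt,
                        materials = vacuum_materials_1d(n_cells))
    xe <- (0:n_cells) * delta
    st$Ez <- sin(k * xe)
    st$Dz <- st$Ez
    st <- run_simulation(st, coeffs, n_steps = steps, boundary = "pec")
    exact <- sin(k * xe) * cos(omega * steps * dt)
    sqrt(sum((st$Ez - exact)^2) / length(xe))
  }, numeric(1))

  if (any(errs < 1e-13)) {
    stop("error sequence reached machine precision; use a coarser setup")
  }
  if (any(diff(errs) >= 0)) {
    stop("error sequence is not decreasing under time refinement")
  }
  lev <- seq_len(levels)
  -unname(stats::coef(stats::lm(log2(errs) ~ lev))[2])
}
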