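# Two-dimensional TE-mode driver around the compiled staged stepper.

#' Grid and time-step specification
#'
#' Computes the time step from the Courant number
#' `courant = c0 * dt * sqrt(dim) / delta` and validates it against the
#' scheme-specific stability limit ([cfl_limit()]).
#'
#' @param dim Dimensionality (1 or 2).
#' @param n Cell counts (length `dim`).
#' @param delta Spatial step, m.
#' @param courant Courant number (dimensionless), default 0.5.
#' @param coeffs Stage coefficients of the intended scheme.
#' @param a1,a2 Spatial stencil weights (fourth-order staggered by default).
#' @return Object of class `grid_spec` with `dt` filled in.
#' @export
#' @examples
#' grid_spec(1, 120, 0.01)
grid_spec <- function(dim, n, delta, courant = 0.5,
                      coeffs = yoshida_coefficients(),
                      a1 = 9 / 8, a2 = -1 / 24) {
  dim <- as.integer(dim)
  stopifnot(dim %in% c(1L, 2L), length(n) == dim, delta > 0, courant > 0)
  s <- courant / sqrt(dim)
  s_max <- cfl_limit(coeffs, dim, a1, a2)
  if (s > s_max + 1e-9) {
    stop(sprintf(
      "CFL violation: c0 dt / delta = %.4f exceeds the scheme limit %.4f",
      s, s_max))
  }
  dt <- courant * delta / (.c0 * sqrt(dim))
  structure(list(dim = dim, n = as.integer(n), delta = delta, dt = dt,
                 courant = courant, cfl_limit = s_max),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d-D, %s cells, delta = %g m, dt = %g s (Courant %.3g, limit %.3g)\n",
              x$dim, paste(x$n, collapse = " x "), x$delta, x$dt,
              x$courant, x$cfl_limit * sqrt(x$dim)))
  invisible(x)
}

# Staggered-point material arrays for the TE grid. Classifies the phantom
# geometry directly at each field component's own location, which preserves
# the exact mirror symmetry of symmetric setups.
staggered_materials_2d <- function(spec, frequency, nx, ny, delta) {
  if (is.null(spec)) {
    return(list(
      exEps = matrix(1, nx, ny + 1L), exSig = matrix(0, nx, ny + 1L),
      exPl = matrix(0L, nx, ny + 1L),
      eyEps = matrix(1, nx + 1L, ny), eySig = matrix(0, nx + 1L, ny),
      eyPl = matrix(0L, nx + 1L, ny),
      fp = 0, nu = 0
    ))
  }
  ex_pts <- expand.grid(x = seq_len(nx) - 0.5, y = 0:ny,
                        KEEP.OUT.ATTRS = FALSE)
  ex <- material_at_units(spec, frequency, ex_pts$x, ex_pts$y)
  ey_pts <- expand.grid(x = 0:nx, y = seq_len(ny) - 0.5,
                        KEEP.OUT.ATTRS = FALSE)
  ey <- material_at_units(spec, frequency, ey_pts$x, ey_pts$y)
  list(
    exEps = matrix(ex$eps_r, nx, ny + 1L),
    exSig = matrix(ex$sigma, nx, ny + 1L),
    exPl = matrix(as.integer(ex$kind == 4L), nx, ny + 1L),
    eyEps = matrix(ey$eps_r, nx + 1L, ny),
    eySig = matrix(ey$sigma, nx + 1L, ny),
    eyPl = matrix(as.integer(ey$kind == 4L), nx + 1L, ny),
    fp = spec$plasma_fp, nu = spec$plasma_nu
  )
}

# Default TF/SF window: the phantom's outer extent plus a margin, mirror
# symmetric about the phantom centre row.
default_tf_window <- function(spec, nx, ny, delta, margin = 8L) {
  r_out <- max(spec$r_uterus, spec$layer_inner_radius + spec$layer_thickness)
  hw <- ceiling(r_out / delta) + margin
  # window chosen mirror-symmetric about the phantom centre line:
  # j0 + j1 == ny - 1 keeps the TF/SF corrections exactly y-symmetric
  i0 <- (nx %/% 2L) - hw
  j0 <- (ny %/% 2L) - hw
  c(i0, nx - 1L - i0, j0, ny - 1L - j0)
}

#' Run a 2-D TE-mode simulation
#'
#' Marches the staged symplectic scheme (or the second-order baseline) on a
#' 2-D staggered grid, optionally with a phantom material map and a
#' total-field/scattered-field plane wave travelling towards +x. Tracks
#' per-cell running peak |Ex| and |Ey| from `track_start` completed steps
#' onwards. Deterministic: identical configurations give bit-identical
#' results.
#'
#' @param phantom A [phantom_spec()] or `NULL` for vacuum.
#' @param frequency Operating frequency, Hz (required with a phantom or
#'   plane-wave source).
#' @param source A [plane_wave_spec()] or `NULL`.
#' @param nx,ny,delta Grid geometry; taken from the phantom when given.
#' @param courant Courant number (`c0 dt sqrt(2) / delta`), default 0.5.
#' @param scheme `"sfdtd"` (fourth-order staggered space, Yoshida stages) or
#'   `"fdtd22"` (two-point stencil, Strang stages).
#' @param coeffs Stage coefficients; defaults chosen by `scheme`.
#' @param n_steps Number of full time steps.
#' @param track_start Completed steps before peak tracking begins.
#' @param tf_window TF/SF window `c(i0, i1, j0, j1)` in cell indices
#'   (0-based, inclusive); default encloses the phantom with an 8-cell margin.
#' @param boundary `"mur"` (absorbing) or `"pec"`.
#' @param probes Optional integer matrix with columns `i`, `j`: Ey probe
#'   locations (0-based), recorded every step.
#' @return Object of class `te2d_result`: final field matrices `Ex`, `Ey`,
#'   `Hz`, peak matrices `peak_ex`, `peak_ey`, probe series, and the run
#'   metadata (`grid`, `frequency`, `materials` cell-centre map when a
#'   phantom was given).
#' @export
run_te2d <- function(phantom = NULL, frequency = NULL, source = NULL,
                     nx = NULL, ny = NULL, delta = NULL, courant = 0.5,
                     scheme = c("sfdtd", "fdtd22"), coeffs = NULL,
                     n_steps, track_start = 0L, tf_window = NULL,
                     boundary = c("mur", "pec"), probes = NULL) {
  scheme <- match.arg(scheme)
  boundary <- match.arg(boundary)
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "phantom_spec"))
    nx <- phantom$nx; ny <- phantom$ny; delta <- phantom$delta
    if (is.null(frequency)) stop("`frequency` is required with a phantom")
  }
  stopifnot(!is.null(nx), !is.null(ny), !is.null(delta), n_steps >= 1)

  if (is.null(coeffs)) {
    coeffs <- if (scheme == "sfdtd") yoshida_coefficients() else leapfrog_coefficients()
  }
  st <- if (scheme == "sfdtd") stencil_coefficients() else list(a1 = 1, a2 = 0)
  grid <- grid_spec(2L, c(nx, ny), delta, courant, coeffs, st$a1, st$a2)

  mats <- staggered_materials_2d(phantom, frequency, nx, ny, delta)

  src_amp <- 0; src_freq <- 1; ramp <- 1
  if (!is.null(source)) {
    stopifnot(inherits(source, "source_spec"), source$kind == "plane_wave")
    src_amp <- source$amplitude
    src_freq <- source$frequency
    ramp <- source$ramp_periods
    if (is.null(tf_window)) {
      if (is.null(phantom)) stop("`tf_window` is required for vacuum plane-wave runs")
      tf_window <- default_tf_window(phantom, nx, ny, delta)
    }
  }
  if (is.null(tf_window)) tf_window <- c(4L, nx - 5L, 4L, ny - 5L)

  if (is.null(probes)) {
    pi_ <- integer(0); pj_ <- integer(0)
  } else {
    probes <- as.matrix(probes)
    pi_ <- as.integer(probes[, 1]); pj_ <- as.integer(probes[, 2])
  }

  out <- .sfdtd2d_run(
    as.integer(nx), as.integer(ny), delta, grid$dt, as.integer(n_steps),
    coeffs$c, coeffs$d, st$a1, st$a2,
    mats$exEps, mats$exSig, mats$exPl, mats$eyEps, mats$eySig, mats$eyPl,
    mats$fp, mats$nu,
    as.integer(tf_window[1]), as.integer(tf_window[2]),
    as.integer(tf_window[3]), as.integer(tf_window[4]),
    src_amp, src_freq, ramp,
    if (boundary == "mur") 0L else 1L,
    as.integer(track_start), pi_, pj_
  )

  structure(
    list(Ex = out$Ex, Ey = out$Ey, Hz = out$Hz,
         peak_ex = out$peak_ex, peak_ey = out$peak_ey,
         probes = out$probes, grid = grid, scheme = scheme,
         frequency = frequency, n_steps = as.integer(n_steps),
         track_start = as.integer(track_start), tf_window = tf_window,
         materials = if (!is.null(phantom)) build_phantom(phantom, frequency) else NULL,
         phantom = phantom),
    class = "te2d_result"
  )
}

#' @export
print.te2d_result <- function(x, ...) {
  cat(sprintf("<te2d_result> %s scheme, %d x %d cells, %d steps (dt = %g s)\n",
              x$scheme, x$grid$n[1], x$grid$n[2], x$n_steps, x$grid$dt))
  if (!is.null(x$frequency)) {
    cat(sprintf("  frequency %g MHz, peak |Ey| = %g V/m\n",
                x$frequency / 1e6, max(x$peak_ey)))
  }
  invisible(x)
}

#' Run a 2-D TM-mode simulation
#'
#' Companion of [run_te2d()] for the TM polarization (out-of-plane `Ez`,
#' in-plane `Hx`, `Hy`) — the polarization in which an incident plane wave
#' drives axial currents in the phantom and the protective shell. Interface
#' and conventions are identical to [run_te2d()]; peak tracking records
#' per-node running maxima of |Ez|.
#'
#' @inheritParams run_te2d
#' @return Object of class `tm2d_result` with fields `Ez`, `Hx`, `Hy`, peak
#'   matrix `peak_ez` (`(nx+1)` x `(ny+1)` nodes) and run metadata.
#' @export
run_tm2d <- function(phantom = NULL, frequency = NULL, source = NULL,
                     nx = NULL, ny = NULL, delta = NULL, courant = 0.5,
                     scheme = c("sfdtd", "fdtd22"), coeffs = NULL,
                     n_steps, track_start = 0L, tf_window = NULL,
                     boundary = c("mur", "pec"), probes = NULL) {
  scheme <- match.arg(scheme)
  boundary <- match.arg(boundary)
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "phantom_spec"))
    nx <- phantom$nx; ny <- phantom$ny; delta <- phantom$delta
    if (is.null(frequency)) stop("`frequency` is required with a phantom")
  }
  stopifnot(!is.null(nx), !is.null(ny), !is.null(delta), n_steps >= 1)

  if (is.null(coeffs)) {
    coeffs <- if (scheme == "sfdtd") yoshida_coefficients() else leapfrog_coefficients()
  }
  st <- if (scheme == "sfdtd") stencil_coefficients() else list(a1 = 1, a2 = 0)
  grid <- grid_spec(2L, c(nx, ny), delta, courant, coeffs, st$a1, st$a2)

  # materials at the Ez nodes (integer grid units: exactly mirror-symmetric)
  if (is.null(phantom)) {
    ezEps <- matrix(1, nx + 1L, ny + 1L)
    ezSig <- matrix(0, nx + 1L, ny + 1L)
    ezPl <- matrix(0L, nx + 1L, ny + 1L)
    fp <- 0; nu <- 0
  } else {
    pts <- expand.grid(x = 0:nx, y = 0:ny, KEEP.OUT.ATTRS = FALSE)
    mz <- material_at_units(phantom, frequency, pts$x, pts$y)
    ezEps <- matrix(mz$eps_r, nx + 1L, ny + 1L)
    ezSig <- matrix(mz$sigma, nx + 1L, ny + 1L)
    ezPl <- matrix(as.integer(mz$kind == 4L), nx + 1L, ny + 1L)
    fp <- phantom$plasma_fp; nu <- phantom$plasma_nu
  }

  src_amp <- 0; src_freq <- 1; ramp <- 1
  if (!is.null(source)) {
    stopifnot(inherits(source, "source_spec"), source$kind == "plane_wave")
    src_amp <- source$amplitude
    src_freq <- source$frequency
    ramp <- source$ramp_periods
    if (is.null(tf_window)) {
      if (is.null(phantom)) stop("`tf_window` is required for vacuum plane-wave runs")
      tf_window <- default_tf_window(phantom, nx, ny, delta)
    }
  }
  if (is.null(tf_window)) tf_window <- c(4L, nx - 5L, 4L, ny - 5L)

  if (is.null(probes)) {
    pi_ <- integer(0); pj_ <- integer(0)
  } else {
    probes <- as.matrix(probes)
    pi_ <- as.integer(probes[, 1]); pj_ <- as.integer(probes[, 2])
  }

  out <- .sfdtd2d_tm_run(
    as.integer(nx), as.integer(ny), delta, grid$dt, as.integer(n_steps),
    coeffs$c, coeffs$d, st$a1, st$a2,
    ezEps, ezSig, ezPl, fp, nu,
    as.integer(tf_window[1]), as.integer(tf_window[2]),
    as.integer(tf_window[3]), as.integer(tf_window[4]),
    src_amp, src_freq, ramp,
    if (boundary == "mur") 0L else 1L,
    as.integer(track_start), pi_, pj_
  )

  structure(
    list(Ez = out$Ez, Hx = out$Hx, Hy = out$Hy,
         peak_ez = out$peak_ez,
         probes = out$probes, grid = grid, scheme = scheme,
         frequency = frequency, n_steps = as.integer(n_steps),
         track_start = as.integer(track_start), tf_window = tf_window,
         materials = if (!is.null(phantom)) build_phantom(phantom, frequency) else NULL,
         phantom = phantom),
    class = "tm2d_result"
  )
}

#' @export
print.tm2d_result <- function(x, ...) {
  cat(sprintf("<tm2d_result> %s scheme, %d x %d cells, %d steps (dt = %g s)\n",
              x$scheme, x$grid$n[1], x$grid$n[2], x$n_steps, x$grid$dt))
  if (!is.null(x$frequency)) {
    cat(sprintf("  frequency %g MHz, peak |Ez| = %g V/m\n",
                x$frequency / 1e6, max(x$peak_ez)))
  }
  invisible(x)
}
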