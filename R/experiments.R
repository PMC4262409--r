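# End-to-end studies: the 1-D PEC-cavity long-term stability benchmark with
# its method-of-images analytic oracle, refinement-order reports, and the
# 2-D SAR shielding-angle study.

#' Analytic waveform of a Gaussian hard source in a PEC cavity
#'
#' Method-of-images d'Alembert solution on `[0, L]` with perfectly conducting
#' walls: the hard source at `x_s` radiates `g(t - |x - x_s| / c0)` in both
#' directions, and each wall reflection inverts the sign. Images at
#' `2 m L + x_s` (positive) and `2 m L - x_s` (negative) are summed, truncated
#' once they cannot reach `(x, t)` within five pulse widths.
#'
#' @param x Positions, m (vectorised).
#' @param t Time, s (scalar).
#' @param spec A [gaussian_source_spec()]; `spec$cell` is interpreted on the
#'   grid via `x_s`.
#' @param x_s Source position, m.
#' @param L Cavity length, m.
#' @param tail_widths Images are truncated once they cannot reach `(x, t)`
#'   within this many pulse widths; the neglected tail is
#'   `exp(-tail_widths^2 / 2)` of the amplitude.
#' @return Field values, V/m.
#' @export
analytic_cavity_waveform <- function(x, t, spec, x_s, L, tail_widths = 5) {
  stopifnot(inherits(spec, "source_spec"), spec$kind == "gaussian_hard")
  reach <- .c0 * t + tail_widths * .c0 * spec$tau
  m_max <- ceiling((reach + L) / (2 * L))
  out <- numeric(length(x))
  for (m in seq(-m_max, m_max)) {
    for (s in c(1, -1)) {
      xi <- 2 * m * L + s * x_s
      dist <- abs(x - xi)
      sel <- dist <= reach
      if (any(sel)) {
        out[sel] <- out[sel] +
          s * gaussian_hard_source(t - dist[sel] / .c0, spec)
      }
    }
  }
  out
}

#' One-dimensional PEC-cavity long-term stability benchmark
#'
#' Runs the staged symplectic scheme and the classic second-order Yee
#' baseline on the same 120-cell PEC cavity with a unit Gaussian hard source,
#' snapshotting at the two checkpoint iterations, and compares each snapshot
#' with the method-of-images analytic waveform. The peak |Ez| at the late
#' checkpoint separates the two schemes: the symplectic run keeps the pulse
#' amplitude while accumulated numerical dispersion distorts the second-order
#' waveform.
#'
#' @param n_cells Cavity size in cells.
#' @param delta Spatial step, m.
#' @param courant Courant number (`c0 dt / delta`).
#' @param amplitude Source amplitude, V/m.
#' @param tau_steps Pulse width in time steps (`tau = tau_steps * dt`).
#' @param t0_factor Pulse centre in widths (`t0 = t0_factor * tau`).
#' @param cell Source node (1-based; default one quarter into the cavity so
#'   wall reflections return only after the hard source has released).
#' @param snapshots Checkpoint iterations.
#' @return Object of class `cavity_benchmark`: `summary` data frame (scheme,
#'   step, peak |Ez|, relative L2 error vs analytic) plus the snapshot and
#'   analytic waveforms.
#' @export
#' @examples
#' \donttest{
#' bench <- cavity1d_benchmark()
#' bench$summary
#' }
cavity1d_benchmark <- function(n_cells = 120L, delta = 0.01, courant = 0.5,
                               amplitude = 1, tau_steps = 12, t0_factor = 5,
                               cell = 31L, snapshots = c(436L, 3146L)) {
  dt <- courant * delta / .c0
  tau <- tau_steps * dt
  t0 <- t0_factor * tau
  src <- gaussian_source_spec(amplitude, t0, tau, cell)
  x_s <- (cell - 1L) * delta
  L <- n_cells * delta
  xe <- (0:n_cells) * delta
  obs <- list(snap = list(at = snapshots, fn = function(s) s$Ez))

  run_one <- function(scheme) {
    st <- init_state_1d(n_cells, delta, dt)
    run_simulation(st, yoshida_coefficients(), max(snapshots),
                   sources = list(src), boundary = "pec",
                   scheme = scheme, observers = obs)
  }
  res <- lapply(c(sfdtd = "sfdtd", fdtd22 = "fdtd22"), run_one)

  rows <- list()
  waveforms <- list()
  for (scheme in names(res)) {
    snaps <- res[[scheme]]$observations$snap
    for (k in seq_along(snaps$steps)) {
      step <- snaps$steps[k]
      ez <- snaps$values[[k]]
      ana <- analytic_cavity_waveform(xe, step * dt, src, x_s, L)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, step = step,
        peak = max(abs(ez)),
        l2_error = sqrt(sum((ez - ana)^2) / sum(ana^2))
      )
      waveforms[[paste(scheme, step, sep = "_")]] <- ez
      waveforms[[paste("analytic", step, sep = "_")]] <- ana
    }
  }
  structure(
    list(summary = do.call(rbind, rows), waveforms = waveforms,
         x = xe, dt = dt, source = src, n_cells = n_cells, delta = delta),
    class = "cavity_benchmark"
  )
}

#' @export
print.cavity_benchmark <- function(x, ...) {
  cat(sprintf("<cavity_benchmark> %d-cell PEC cavity, dt = %g s\n",
              x$n_cells, x$dt))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Refinement-order report
#'
#' Spatial order: the staged fourth-order scheme on a 1-D PEC-cavity standing
#' mode at fixed Courant number, with the grid refined by successive halving
#' and the final-time L2 error measured against the closed-form mode; the
#' fitted slope combines the (equal-order) spatial and temporal errors.
#' Temporal orders: [empirical_order()] for the Yoshida set and the
#' second-order Strang control.
#'
#' @param n_base Coarsest grid size in cells.
#' @param levels Number of refinement levels.
#' @param mode Standing-mode index.
#' @param courant Courant number.
#' @return List with `spatial_order`, `temporal_order_sfdtd`,
#'   `temporal_order_leapfrog`, and the spatial error sequence.
#' @export
#' @examples
#' \donttest{
#' convergence_report(levels = 3)
#' }
convergence_report <- function(n_base = 24L, levels = 4L, mode = 3L,
                               courant = 0.5) {
  errs <- vapply(seq_len(levels), function(lev) {
    n <- n_base * 2^(lev - 1L)
    delta <- 1 / n  # fixed physical cavity length L = 1 m
    L <- 1
    k <- mode * pi / L
    omega <- .c0 * k
    # generic phase: at a full period the field sits at a cosine extremum and
    # the dominant (frequency-shift) error would enter only quadratically
    t_final <- 0.37 * 2 * pi / omega
    steps <- ceiling(t_final / (courant * delta / .c0))
    dt <- t_final / steps
    st <- init_state_1d(n, delta, dt)
    xe <- (0:n) * delta
    st$Ez <- sin(k * xe)
    st$Dz <- st$Ez
    st <- run_simulation(st, yoshida_coefficients(), steps, boundary = "pec")
    exact <- sin(k * xe) * cos(omega * t_final)
    sqrt(sum((st$Ez - exact)^2) / (n + 1))
  }, numeric(1))
  lev <- seq_len(levels)
  spatial <- -unname(stats::coef(stats::lm(log2(errs) ~ lev))[2])
  list(
    spatial_order = spatial,
    spatial_errors = errs,
    temporal_order_sfdtd = empirical_order(yoshida_coefficients(), 4L),
    temporal_order_leapfrog = empirical_order(leapfrog_coefficients(), 4L)
  )
}

#' SAR of a finished 2-D run
#'
#' Convenience wrapper: tracked peaks ([track_peaks()]) fed into
#' [compute_sar()] with the run's own material map.
#'
#' @param result A `te2d_result` from [run_te2d()] with a phantom.
#' @return A `sar_map`.
#' @export
sar_from_run <- function(result) {
  stopifnot(inherits(result, c("te2d_result", "tm2d_result")))
  if (is.null(result$materials)) stop("run has no phantom material map")
  pk <- track_peaks(result)
  if (inherits(result, "tm2d_result")) {
    # TM: the single out-of-plane component carries all the absorbed power
    compute_sar(pk$peak_ez, 0 * pk$peak_ez, result$materials)
  } else {
    compute_sar(pk$peak_ex, pk$peak_ey, result$materials)
  }
}

#' Shielding-angle SAR study
#'
#' For each frequency and plasma-layer angle: builds the phantom, runs the
#' staged scheme to steady state under a unit plane wave (smooth-started,
#' with a warm-up before peak tracking over the final full period), computes
#' the SAR map with its axis profiles, and tabulates the percent reductions
#' of the profile peaks relative to the unshielded (0 degree) run at the same
#' frequency.
#'
#' The `"desk"` scale uses a 225 x 225 grid at 4 mm with one warm-up period;
#' `"full"` uses the 450 x 450 grid at 2 mm with two warm-up periods.
#'
#' @param frequencies Frequencies, Hz (subset of 64e6, 128e6).
#' @param angles Plasma-layer angular extents, degrees.
#' @param scale `"desk"` or `"full"`, or `NULL` to use a custom `spec_fn`.
#' @param spec_fn Optional `function(angle)` returning a [phantom_spec()];
#'   overrides `scale`.
#' @param mode Polarization: `"tm"` (out-of-plane Ez, the field the 2-D
#'   snapshot study displays; default) or `"te"` (in-plane Ex/Ey). At these
#'   frequencies the phantom is deeply sub-wavelength and only the TM mode
#'   drives axial currents in the protective shell, so shielding is
#'   essentially a TM effect; see the methods vignette.
#' @param warmup_periods Warm-up periods before peak tracking (default by
#'   scale).
#' @param track_periods Peak-tracking window, periods.
#' @param courant Courant number.
#' @param keep_maps Keep the full `sar_map` objects in the result.
#' @return Object of class `shielding_study`: `summary` data frame with
#'   columns `frequency`, `angle`, `peak_sarx`, `peak_sary`, `peak_sar`,
#'   `reduction_x`, `reduction_y` (percent vs 0 degrees), and optionally
#'   `maps`.
#' @export
#' @examples
#' \donttest{
#' study <- sar_study(frequencies = 64e6, angles = c(0, 60), scale = "desk")
#' study$summary
#' }
sar_study <- function(frequencies = c(64e6, 128e6),
                      angles = c(0, 60, 90, 120, 180),
                      scale = c("desk", "full"), spec_fn = NULL,
                      mode = c("tm", "te"),
                      warmup_periods = NULL, track_periods = 1,
                      courant = 0.5, keep_maps = TRUE) {
  mode <- match.arg(mode)
  run_fn <- if (mode == "tm") run_tm2d else run_te2d
  if (is.null(spec_fn)) {
    scale <- match.arg(scale)
    if (is.null(warmup_periods)) {
      warmup_periods <- if (scale == "desk") 1 else 2
    }
    spec_fn <- if (scale == "desk") {
      function(angle) phantom_spec(nx = 225L, ny = 225L, delta = 4e-3,
                                   layer_angle = angle)
    } else {
      function(angle) phantom_spec(nx = 450L, ny = 450L, delta = 2e-3,
                                   layer_angle = angle)
    }
  } else if (is.null(warmup_periods)) {
    warmup_periods <- 1
  }

  rows <- list()
  maps <- list()
  for (freq in frequencies) {
    base_x <- NA_real_; base_y <- NA_real_
    for (angle in angles) {
      spec <- spec_fn(angle)
      dt <- courant * spec$delta / (.c0 * sqrt(2))
      spp <- ceiling((1 / freq) / dt)
      warm <- ceiling(warmup_periods * spp)
      total <- warm + ceiling(track_periods * spp)
      run <- run_fn(phantom = spec, frequency = freq,
                    source = plane_wave_spec(1, freq),
                    courant = courant, n_steps = total, track_start = warm)
      sm <- sar_from_run(run)
      if (angle == 0) { base_x <- sm$peak_sarx; base_y <- sm$peak_sary }
      rows[[length(rows) + 1L]] <- data.frame(
        frequency = freq, angle = angle,
        peak_sarx = sm$peak_sarx, peak_sary = sm$peak_sary,
        peak_sar = sm$peak_sar,
        reduction_x = if (is.na(base_x)) NA_real_ else reduction_percent(base_x, sm$peak_sarx),
        reduction_y = if (is.na(base_y)) NA_real_ else reduction_percent(base_y, sm$peak_sary)
      )
      if (keep_maps) maps[[sprintf("f%g_a%g", freq / 1e6, angle)]] <- sm
    }
  }
  structure(list(summary = do.call(rbind, rows), maps = maps),
            class = "shielding_study")
}

#' @export
print.shielding_study <- function(x, ...) {
  cat("<shielding_study>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
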