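# One-dimensional staggered-grid solver: staged symplectic stepper with
# fourth-order stencils, classic second-order Yee baseline, PEC/Mur
# boundaries, observers and the quadratic energy diagnostic.
#
# Layout: Ez (and Dz) live on nodes x_j = (j - 1) * delta, j = 1..n+1;
# Hy lives on staggered half-nodes x_{j+1/2}, stored at index h = 1..n.
# Fields are stored in E-units (Hy holds Z0 * H) so both curl updates carry
# a factor c0 and a vacuum plane wave has numerically equal Ez and Hy.

#' Homogeneous material description for a 1-D grid
#'
#' @param n Number of cells (the grid has `n + 1` electric-field nodes).
#' @param eps_r Relative permittivity (scalar or per-node vector).
#' @param sigma Conductivity, S/m (scalar or per-node vector).
#' @return List with per-node `eps_r`, `sigma`, logical `plasma` mask and
#'   plasma parameters (`fp`, `nu`, both 0 here).
#' @export
vacuum_materials_1d <- function(n, eps_r = 1, sigma = 0) {
  list(eps_r = rep_len(eps_r, n + 1L), sigma = rep_len(sigma, n + 1L),
       plasma = rep_len(FALSE, n + 1L), fp = 0, nu = 0)
}

#' Material description with a homogeneous slab insert
#'
#' Builds per-node 1-D materials that are vacuum outside the index range
#' `slab` and either a Drude plasma (if `fp > 0`) or a lossy dielectric
#' inside it.
#'
#' @param n Number of cells.
#' @param slab Integer vector of node indices occupied by the slab.
#' @param eps_r,sigma Dielectric parameters of the slab material.
#' @param fp,nu Drude plasma and collision frequencies, Hz; `fp > 0` marks
#'   the slab nodes as plasma (with `eps_r = 1`, `sigma = 0`).
#' @return Material list as in [vacuum_materials_1d()].
#' @export
slab_materials_1d <- function(n, slab, eps_r = 1, sigma = 0, fp = 0, nu = 0) {
  m <- vacuum_materials_1d(n)
  if (fp > 0) {
    m$plasma[slab] <- TRUE
    m$fp <- fp
    m$nu <- nu
  } else {
    m$eps_r[slab] <- eps_r
    m$sigma[slab] <- sigma
  }
  m
}

#' Initialise a 1-D field state
#'
#' @param n Number of cells.
#' @param delta Spatial step, m.
#' @param dt Time step, s.
#' @param materials Per-node materials, see [vacuum_materials_1d()].
#' @return Object of class `fdtd_state_1d` with zeroed fields.
#' @export
init_state_1d <- function(n, delta, dt, materials = vacuum_materials_1d(n)) {
  n <- as.integer(n)
  stopifnot(n >= 4L, delta > 0, dt > 0)
  stopifnot(length(materials$eps_r) == n + 1L)
  structure(
    list(n = n, delta = delta, dt = dt,
         Ez = numeric(n + 1L), Dz = numeric(n + 1L), Hy = numeric(n),
         accum = numeric(n + 1L), Jz = numeric(n + 1L),
         materials = materials, step = 0L, time = 0),
    class = "fdtd_state_1d"
  )
}

#' @export
print.fdtd_state_1d <- function(x, ...) {
  cat(sprintf("<fdtd_state_1d> %d cells, delta = %g m, dt = %g s, step %d (t = %g s)\n",
              x$n, x$delta, x$dt, x$step, x$time))
  cat(sprintf("  max |Ez| = %g V/m\n", max(abs(x$Ez))))
  invisible(x)
}

# Staggered derivative of Ez at half-nodes h = 1..n.
# PEC walls use image-theory ghosts (Ez odd across the wall), keeping the
# stencil uniformly fourth order; absorbing boundaries fall back to the
# second-order difference in the outermost half-nodes.
curl_e_1d <- function(Ez, delta, boundary) {
  n <- length(Ez) - 1L
  a <- stencil_coefficients()
  d <- numeric(n)
  h <- 2:(n - 1L)
  d[h] <- (a$a1 * (Ez[h + 1L] - Ez[h]) + a$a2 * (Ez[h + 2L] - Ez[h - 1L])) / delta
  if (boundary == "pec") {
    d[1L] <- (a$a1 * (Ez[2L] - Ez[1L]) + a$a2 * (Ez[3L] + Ez[2L])) / delta
    d[n] <- (a$a1 * (Ez[n + 1L] - Ez[n]) + a$a2 * (-Ez[n] - Ez[n - 1L])) / delta
  } else {
    d[1L] <- (Ez[2L] - Ez[1L]) / delta
    d[n] <- (Ez[n + 1L] - Ez[n]) / delta
  }
  d
}

# Staggered derivative of Hy at interior nodes j = 2..n (length n + 1 output;
# boundary nodes are handled by the boundary condition and left at zero).
curl_h_1d <- function(Hy, delta, boundary) {
  n <- length(Hy)
  a <- stencil_coefficients()
  d <- numeric(n + 1L)
  j <- 3:(n - 1L)
  d[j] <- (a$a1 * (Hy[j] - Hy[j - 1L]) + a$a2 * (Hy[j + 1L] - Hy[j - 2L])) / delta
  if (boundary == "pec") {
    d[2L] <- (a$a1 * (Hy[2L] - Hy[1L]) + a$a2 * (Hy[3L] - Hy[1L])) / delta
    d[n] <- (a$a1 * (Hy[n] - Hy[n - 1L]) + a$a2 * (Hy[n] - Hy[n - 2L])) / delta
  } else {
    d[2L] <- (Hy[2L] - Hy[1L]) / delta
    d[n] <- (Hy[n] - Hy[n - 1L]) / delta
  }
  d
}

apply_sources_1d <- function(state, sources, t, dt_sub) {
  for (src in sources) {
    if (src$kind == "gaussian_hard") {
      if (t <= src$active_until) {
        g <- gaussian_hard_source(t, src)
        state$Ez[src$cell] <- g
        state$Dz[src$cell] <- state$materials$eps_r[src$cell] * g
      }
    } else if (src$kind == "sine_soft") {
      g <- ramped_sine(t, src$amplitude, src$frequency, src$ramp_periods) * dt_sub
      state$Ez[src$cell] <- state$Ez[src$cell] +
        g / state$materials$eps_r[src$cell]
      state$Dz[src$cell] <- state$Dz[src$cell] + g
    } else {
      stop(sprintf("source kind '%s' is not supported on 1-D grids", src$kind))
    }
  }
  state
}

apply_e_boundary_1d <- function(state, boundary, old_ez = NULL, dt_sub = NULL) {
  n <- state$n
  if (boundary == "pec") {
    state$Ez[c(1L, n + 1L)] <- 0
    state$Dz[c(1L, n + 1L)] <- 0
  } else if (boundary == "mur" && !is.null(old_ez)) {
    # first-order Mur, applied per (sub-)step with the sub-step-scaled
    # coefficient; for the staged scheme this is done after every electric
    # stage, which absorbs cleanly where a once-per-step application would
    # partially reflect off the stale boundary value
    if (is.null(dt_sub)) dt_sub <- state$dt
    K <- (.c0 * dt_sub - state$delta) / (.c0 * dt_sub + state$delta)
    state$Ez[1L] <- old_ez[2L] + K * (state$Ez[2L] - old_ez[1L])
    state$Ez[n + 1L] <- old_ez[n] + K * (state$Ez[n] - old_ez[n + 1L])
    state$Dz[1L] <- state$materials$eps_r[1L] * state$Ez[1L]
    state$Dz[n + 1L] <- state$materials$eps_r[n + 1L] * state$Ez[n + 1L]
  }
  state
}

#' Advance a 1-D state by one full staged time step
#'
#' Applies the `m` stages of the split-operator composition: stage `l`
#' advances the flux density (and hence the electric field through the
#' dispersive constitutive update, minus any plasma-current contribution) by
#' `c[l] * dt` using the staggered curl of `Hy`, then advances `Hy` by
#' `d[l] * dt` using the staggered curl of `Ez`. Hard/soft sources are applied
#' after each electric stage at the accumulated stage time; the boundary
#' condition is enforced after every stage (Mur once per full step).
#'
#' @param state A [init_state_1d()] state.
#' @param coeffs Stage coefficients, e.g. [yoshida_coefficients()].
#' @param sources List of [gaussian_source_spec()] / [sine_soft_source_spec()].
#' @param boundary `"pec"` or `"mur"`.
#' @return The advanced state (step + 1).
#' @export
advance_step <- function(state, coeffs, sources = list(), boundary = "pec") {
  stopifnot(inherits(state, "fdtd_state_1d"),
            inherits(coeffs, "stage_coefficients"))
  boundary <- match.arg(boundary, c("pec", "mur"))
  mat <- state$materials
  n <- state$n
  dt <- state$dt
  t_e <- state$time
  has_plasma <- any(mat$plasma)
  has_loss <- any(mat$sigma > 0)
  pl <- which(mat$plasma)

  # Conduction loss and the plasma current are applied once per full step
  # (at the final electric stage, with the frozen running sum / current used
  # in the earlier stages). Applying them per sub-step is inconsistent with
  # backward (negative) stages: the loss term turns into gain there and the
  # composition with the rotation is unstable.
  last_e <- max(which(coeffs$c != 0))
  for (l in seq_len(coeffs$m)) {
    cl <- coeffs$c[l]
    if (cl != 0) {
      dts <- cl * dt
      old_ez <- if (boundary == "mur") state$Ez else NULL
      dH <- curl_h_1d(state$Hy, state$delta, boundary)
      state$Dz <- state$Dz - dts * .c0 * dH
      if (has_plasma) {
        state$Dz[pl] <- state$Dz[pl] - dts * state$Jz[pl] / .eps0
      }
      if (has_loss) {
        upd <- dispersive_e_update(state$Dz, state$accum, mat$eps_r,
                                   mat$sigma, dt)
        state$Ez <- upd$E
        if (l == last_e) {
          lossy <- mat$sigma > 0
          state$accum[lossy] <- upd$accum[lossy]
        }
      } else {
        state$Ez <- state$Dz / mat$eps_r
      }
      if (has_plasma && l == last_e) {
        state$Jz[pl] <- drude_current_update(state$Jz[pl], state$Ez[pl],
                                             mat$fp, mat$nu, dt)
      }
      t_e <- t_e + dts
      state <- apply_sources_1d(state, sources, t_e, dts)
      state <- apply_e_boundary_1d(state, boundary, old_ez, dts)
    }
    dl <- coeffs$d[l]
    if (dl != 0) {
      dE <- curl_e_1d(state$Ez, state$delta, boundary)
      state$Hy <- state$Hy - dl * dt * .c0 * dE
    }
  }
  state$step <- state$step + 1L
  state$time <- state$time + dt
  if (!is.finite(state$Ez[(n %/% 2) + 1L]) || !all(is.finite(state$Ez))) {
    stop(sprintf("instability detected: non-finite field at step %d", state$step))
  }
  state
}

#' Advance a 1-D state by one classic Yee FDTD(2,2) step
#'
#' The traditional second-order leapfrog baseline: `Hy` (living at half time
#' steps) is advanced with the two-point staggered curl of `Ez`, then `Dz`/`Ez`
#' with the two-point curl of `Hy`, sharing the same dispersive constitutive
#' and plasma updates as the staged scheme. At Courant number 1 this scheme is
#' exact in 1-D vacuum (the "magic time step").
#'
#' @inheritParams advance_step
#' @return The advanced state.
#' @export
fdtd22_step <- function(state, sources = list(), boundary = "pec") {
  stopifnot(inherits(state, "fdtd_state_1d"))
  boundary <- match.arg(boundary, c("pec", "mur"))
  mat <- state$materials
  n <- state$n
  dt <- state$dt
  old_ez <- if (boundary == "mur") state$Ez else NULL

  dE <- (state$Ez[2:(n + 1L)] - state$Ez[1:n]) / state$delta
  state$Hy <- state$Hy - dt * .c0 * dE

  dH <- numeric(n + 1L)
  j <- 2:n
  dH[j] <- (state$Hy[j] - state$Hy[j - 1L]) / state$delta
  state$Dz <- state$Dz - dt * .c0 * dH
  pl <- which(mat$plasma)
  if (length(pl)) {
    state$Dz[pl] <- state$Dz[pl] - dt * state$Jz[pl] / .eps0
  }
  if (any(mat$sigma > 0)) {
    upd <- dispersive_e_update(state$Dz, state$accum, mat$eps_r, mat$sigma, dt)
    state$Ez <- upd$E
    lossy <- mat$sigma > 0
    state$accum[lossy] <- upd$accum[lossy]
  } else {
    state$Ez <- state$Dz / mat$eps_r
  }
  if (length(pl)) {
    state$Jz[pl] <- drude_current_update(state$Jz[pl], state$Ez[pl],
                                         mat$fp, mat$nu, dt)
  }

  t_new <- state$time + dt
  state <- apply_sources_1d(state, sources, t_new, dt)
  state <- apply_e_boundary_1d(state, boundary, old_ez)
  state$step <- state$step + 1L
  state$time <- t_new
  if (!all(is.finite(state$Ez))) {
    stop(sprintf("instability detected: non-finite field at step %d", state$step))
  }
  state
}

#' Run a 1-D simulation for a number of steps
#'
#' Iterates [advance_step()] (scheme `"sfdtd"`) or [fdtd22_step()]
#' (`"fdtd22"`), invoking observers at their cadence. Fully deterministic:
#' identical inputs give bit-identical fields.
#'
#' @param state Initial state from [init_state_1d()].
#' @param coeffs Stage coefficients (ignored for scheme `"fdtd22"`).
#' @param n_steps Number of steps (>= 1).
#' @param sources List of source specifications.
#' @param boundary `"pec"` or `"mur"`.
#' @param scheme `"sfdtd"` (staged, fourth-order space) or `"fdtd22"`.
#' @param observers Named list; each element is a list with `fn(state)` and
#'   either `every` (cadence in steps) or `at` (specific step indices).
#' @return List with the final `state` and `observations` (per observer, a
#'   list with `steps` and `values`).
#' @export
#' @examples
#' st <- init_state_1d(64, 0.01, 0.5 * 0.01 / physical_constants()$c0)
#' src <- gaussian_source_spec(1, t0 = 6e-10, tau = 1.2e-10, cell = 17)
#' out <- run_simulation(st, yoshida_coefficients(), 100, sources = list(src))
#' max(abs(out$state$Ez))
run_simulation <- function(state, coeffs = yoshida_coefficients(), n_steps,
                           sources = list(), boundary = "pec",
                           scheme = c("sfdtd", "fdtd22"),
                           observers = list()) {
  scheme <- match.arg(scheme)
  if (n_steps < 1) stop("`n_steps` must be >= 1")
  obs_out <- lapply(observers, function(o) list(steps = integer(), values = list()))
  for (s in seq_len(n_steps)) {
    state <- if (scheme == "sfdtd") {
      advance_step(state, coeffs, sources, boundary)
    } else {
      fdtd22_step(state, sources, boundary)
    }
    for (nm in names(observers)) {
      o <- observers[[nm]]
      hit <- (!is.null(o$every) && s %% o$every == 0L) ||
        (!is.null(o$at) && s %in% o$at)
      if (hit) {
        obs_out[[nm]]$steps <- c(obs_out[[nm]]$steps, s)
        obs_out[[nm]]$values[[length(obs_out[[nm]]$values) + 1L]] <- o$fn(state)
      }
    }
  }
  if (length(observers) == 0L) return(state)
  list(state = state, observations = obs_out)
}

#' Total electromagnetic field energy of a 1-D state
#'
#' Quadratic energy `0.5 * sum(eps |E|^2 + mu0 |H|^2) * delta` per unit
#' cross-sectional area (J/m^2). Conduction and plasma energy channels are not
#' included, so in a lossy closed cavity this diagnostic is non-increasing
#' after source switch-off, and in a lossless one it is conserved up to the
#' integrator's bounded oscillation.
#'
#' @param state A 1-D state.
#' @return Energy per unit area, J/m^2.
#' @export
total_energy <- function(state) {
  stopifnot(inherits(state, "fdtd_state_1d"))
  0.5 * state$delta * .eps0 *
    (sum(state$materials$eps_r * state$Ez^2) + sum(state$Hy^2))
}
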