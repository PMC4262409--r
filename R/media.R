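# Constitutive updates: lossy dispersive tissue via the (D, E) running-sum
# formulation, and the Drude plasma current.

#' Dispersive (D, E) electric-field update with conductivity running sum
#'
#' Recovers the electric field from the normalized flux density in a lossy
#' dielectric. Conduction loss enters through a running sum of past electric
#' field values:
#' `E = (D - (sigma * dt / eps0) * accum) / (eps_r + sigma * dt / eps0)`,
#' after which the accumulator is incremented by `E`. For `sigma = 0` this is
#' exactly the instantaneous law `E = D / eps_r`.
#'
#' `D` is the flux density normalized by `eps0` so that it carries the units
#' of the electric field (V/m) and equals `eps_r * E` in a lossless medium.
#'
#' @param D Normalized flux density value(s), V/m.
#' @param accum Running sum of past `E` values, V/m.
#' @param eps_r Relative permittivity (> 0).
#' @param sigma Conductivity, S/m (>= 0).
#' @param dt_sub Update interval, s. Within a staged integrator this is the
#'   stage sub-step `c[l] * dt`, which may be negative for compositions with
#'   backward stages; the update remains well defined as long as the effective
#'   denominator stays positive.
#' @return List with `E` (the electric field, V/m) and `accum` (the updated
#'   running sum).
#' @export
#' @examples
#' dispersive_e_update(0.5, 0, eps_r = 2, sigma = 0, dt_sub = 1e-12)
dispersive_e_update <- function(D, accum, eps_r, sigma, dt_sub) {
  if (any(eps_r <= 0)) stop("`eps_r` must be > 0")
  if (any(sigma < 0)) stop("`sigma` must be >= 0")
  q <- sigma * dt_sub / .eps0
  E <- (D - q * accum) / (eps_r + q)
  list(E = E, accum = accum + E)
}

#' Drude plasma current update (exponential one-step rule)
#'
#' Advances the auxiliary differential equation
#' `dJ/dt + nu J = eps0 (2 pi fp)^2 E` holding `E` fixed over the
#' interval, which is exact in `J`:
#' `J' = alpha J + beta E` with `alpha = exp(-nu dt)` and
#' `beta = eps0 (2 pi fp)^2 (1 - alpha) / nu`. In the collisionless
#' limit `nu -> 0`, `beta -> eps0 (2 pi fp)^2 dt`.
#'
#' Conventions: the plasma frequency is cyclic (`omega_p = 2 pi fp`), while
#' the collision frequency is the Drude collision rate `nu = 1/tau` in 1/s,
#' entering the model without a 2 pi factor — the standard plasma-physics
#' reading of quoted values such as "plasma frequency 3 GHz, collision
#' frequency 10 GHz".
#'
#' @param J Current density value(s), A/m^2.
#' @param E Electric field value(s), V/m.
#' @param fp Plasma frequency, Hz (>= 0), cyclic.
#' @param nu Collision rate, 1/s (>= 0).
#' @param dt_sub Update interval, s (stage sub-steps may be negative).
#' @return Updated current density `J'`, A/m^2.
#' @export
#' @examples
#' drude_current_update(0, 1, fp = 3e9, nu = 10e9, dt_sub = 1e-12)
drude_current_update <- function(J, E, fp, nu, dt_sub) {
  if (fp < 0 || nu < 0) stop("`fp` and `nu` must be >= 0")
  wp <- 2 * pi * fp
  nr <- nu
  if (nr == 0) {
    beta <- .eps0 * wp^2 * dt_sub
    alpha <- 1
  } else {
    alpha <- exp(-nr * dt_sub)
    beta <- .eps0 * wp^2 * (1 - alpha) / nr
  }
  alpha * J + beta * E
}

#' Drude relative permittivity
#'
#' Analytic complex relative permittivity of a collisional plasma,
#' `eps(omega) = 1 - omega_p^2 / (omega (omega - i nu))`, with
#' `omega = 2 pi f`, `omega_p = 2 pi fp`, and `nu` the collision rate in 1/s
#' (no 2 pi factor; see [drude_current_update()] for the conventions). Used
#' as the reference oracle for slab reflectance/transmission checks.
#'
#' @param f Frequency, Hz (> 0).
#' @param fp Plasma frequency, Hz (cyclic).
#' @param nu Collision rate, 1/s.
#' @return Complex relative permittivity.
#' @export
#' @examples
#' drude_permittivity(64e6, 3e9, 10e9)
drude_permittivity <- function(f, fp, nu) {
  if (any(f <= 0)) stop("`f` must be > 0")
  w <- 2 * pi * f
  wp <- 2 * pi * fp
  1 - wp^2 / (w * (w - 1i * nu))
}

#' Analytic slab transmission coefficient
#'
#' Complex amplitude transmission through a homogeneous slab of thickness `d`
#' and complex relative permittivity `eps_r`, embedded in vacuum, at normal
#' incidence (transfer-matrix form). Serves as the independent oracle for the
#' time-domain plasma slab simulation.
#'
#' @param f Frequency, Hz.
#' @param eps_r Complex relative permittivity of the slab.
#' @param d Slab thickness, m.
#' @return Complex transmission coefficient (field ratio just behind the slab
#'   to the incident field at the front face).
#' @export
slab_transmission <- function(f, eps_r, d) {
  k0 <- 2 * pi * f / .c0
  n <- sqrt(eps_r)
  # branch with decaying wave (positive imaginary index convention e^{-i w t})
  if (Im(n) > 0) n <- -n
  phi <- n * k0 * d
  # characteristic-matrix result; reduces to e^{-i k0 d} for n = 1
  2 / (2 * cos(phi) + 1i * (n + 1 / n) * sin(phi))
}
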