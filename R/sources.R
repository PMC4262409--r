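# Analytic source specifications and evaluators.

#' Gaussian hard-source specification
#'
#' A hard (Dirichlet) source overwrites the electric field at one grid node
#' with `amplitude * exp(-(t - t0)^2 / (2 tau^2))`. The overwrite is active
#' for `t <= t0 + active_factor * tau`; afterwards the node evolves freely so
#' that returning reflections pass through the source location unimpeded.
#'
#' @param amplitude Peak amplitude, V/m.
#' @param t0 Pulse centre time, s.
#' @param tau Pulse width (standard deviation), s (> 0).
#' @param cell Injection node index (1-based electric-field node).
#' @param active_factor Width multiples after `t0` during which the node is
#'   forced; the residual at release is `exp(-active_factor^2 / 2)`.
#' @return Object of class `source_spec`, kind `"gaussian_hard"`.
#' @export
#' @examples
#' gaussian_source_spec(1, t0 = 1e-9, tau = 2e-10, cell = 31)
gaussian_source_spec <- function(amplitude, t0, tau, cell, active_factor = 5) {
  if (tau <= 0) stop("`tau` must be > 0")
  structure(
    list(kind = "gaussian_hard", amplitude = amplitude, t0 = t0, tau = tau,
         cell = as.integer(cell), active_until = t0 + active_factor * tau),
    class = "source_spec"
  )
}

#' Evaluate a Gaussian hard source
#'
#' @param t Time, s (vectorised).
#' @param spec A [gaussian_source_spec()].
#' @return Source field value(s), V/m.
#' @export
#' @examples
#' s <- gaussian_source_spec(1, 1e-9, 2e-10, 31)
#' gaussian_hard_source(1e-9, s) # == amplitude at t0
gaussian_hard_source <- function(t, spec) {
  stopifnot(inherits(spec, "source_spec"), spec$kind == "gaussian_hard")
  spec$amplitude * exp(-(t - spec$t0)^2 / (2 * spec$tau^2))
}

#' Additive (soft) sinusoidal source specification
#'
#' Injects a current-like additive term at one node; unlike a hard source it
#' is transparent to waves passing through the injection cell. The amplitude
#' ramps smoothly over `ramp_periods` periods.
#'
#' @param amplitude Drive amplitude (V/m per second of applied sub-step).
#' @param frequency Drive frequency, Hz (> 0).
#' @param cell Injection node index.
#' @param ramp_periods Smooth-start duration in periods.
#' @return Object of class `source_spec`, kind `"sine_soft"`.
#' @export
sine_soft_source_spec <- function(amplitude, frequency, cell, ramp_periods = 1) {
  if (frequency <= 0) stop("`frequency` must be > 0")
  structure(
    list(kind = "sine_soft", amplitude = amplitude, frequency = frequency,
         cell = as.integer(cell), ramp_periods = ramp_periods),
    class = "source_spec"
  )
}

#' Plane-wave source specification for 2-D runs
#'
#' A monochromatic plane wave travelling towards +x, injected through a
#' total-field/scattered-field (TF/SF) rectangular window that must enclose
#' the phantom. The amplitude ramps smoothly (raised cosine) over
#' `ramp_periods` periods to limit start-up transients.
#'
#' @param amplitude Steady-state electric-field amplitude, V/m.
#' @param frequency Frequency, Hz (> 0).
#' @param ramp_periods Smooth-start duration in periods.
#' @return Object of class `source_spec`, kind `"plane_wave"`.
#' @export
plane_wave_spec <- function(amplitude = 1, frequency, ramp_periods = 1) {
  if (frequency <= 0) stop("`frequency` must be > 0")
  structure(
    list(kind = "plane_wave", amplitude = amplitude, frequency = frequency,
         ramp_periods = ramp_periods),
    class = "source_spec"
  )
}

# Smooth-started sinusoid used for the incident plane wave; u is retarded time.
ramped_sine <- function(u, amplitude, frequency, ramp_periods) {
  ramp_t <- ramp_periods / frequency
  r <- ifelse(u <= 0, 0, ifelse(u >= ramp_t, 1, 0.5 * (1 - cos(pi * u / ramp_t))))
  amplitude * r * sin(2 * pi * frequency * u)
}
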