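# Physical constants (SI, CODATA 2018).
# Fields are stored internally in "E-units": electric fields in V/m and the
# magnetic field scaled as Z0 * H, so that a travelling plane wave has equal
# numeric E and scaled-H amplitudes and both curl updates carry a factor c0.
.c0 <- 299792458
.eps0 <- 8.8541878128e-12
.mu0 <- 1.25663706212e-6
.z0 <- sqrt(.mu0 / .eps0)

#' Physical constants used by the solver
#'
#' @return Named list with `c0` (vacuum speed of light, m/s), `eps0` (vacuum
#'   permittivity, F/m), `mu0` (vacuum permeability, H/m) and `z0` (vacuum
#'   impedance, Ohm).
#' @export
#' @examples
#' physical_constants()$c0
physical_constants <- function() {
  list(c0 = .c0, eps0 = .eps0, mu0 = .mu0, z0 = .z0)
}
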