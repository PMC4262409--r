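# Shared helpers for the test suite. Everything is generated in code; no
# stored fixtures.

C0 <- physical_constants()$c0
EPS0 <- physical_constants()$eps0
Z0 <- physical_constants()$z0

# Small PEC cavity driven by a unit Gaussian hard source; returns the state
# after n_steps under the requested scheme.
run_cavity <- function(n_steps, n_cells = 120L, delta = 0.01, courant = 0.5,
                       cell = 31L, scheme = "sfdtd",
                       materials = vacuum_materials_1d(n_cells),
                       active_factor = 5) {
  dt <- courant * delta / C0
  src <- gaussian_source_spec(1, t0 = 5 * 12 * dt, tau = 12 * dt, cell = cell,
                              active_factor = active_factor)
  st <- init_state_1d(n_cells, delta, dt, materials)
  run_simulation(st, yoshida_coefficients(), n_steps, sources = list(src),
                 boundary = "pec", scheme = scheme)
}

# Mini phantom used by the 2-D property tests: coarse but honours the full
# phantom proportions (radii 100/150/180 mm, layer at 190-210 mm).
mini_phantom <- function(angle) {
  phantom_spec(nx = 101L, ny = 101L, delta = 8e-3, layer_angle = angle)
}

# One steady-state mini SAR run (warm-up one period, track one period).
mini_sar <- function(angle, frequency = 64e6, mode = "tm") {
  spec <- mini_phantom(angle)
  dt <- 0.5 * spec$delta / (C0 * sqrt(2))
  spp <- ceiling((1 / frequency) / dt)
  run_fn <- if (mode == "tm") run_tm2d else run_te2d
  run <- run_fn(phantom = spec, frequency = frequency,
                source = plane_wave_spec(1, frequency),
                n_steps = 2L * spp, track_start = spp)
  sar_from_run(run)
}

# Cache expensive 2-D runs across test files within one session.
.sar_cache <- new.env(parent = emptyenv())
mini_sar_cached <- function(angle, frequency = 64e6, mode = "tm") {
  key <- sprintf("%s_%g_%g", mode, frequency, angle)
  if (is.null(.sar_cache[[key]])) {
    .sar_cache[[key]] <- mini_sar(angle, frequency, mode)
  }
  .sar_cache[[key]]
}
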