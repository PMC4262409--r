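test_that("zero fields stay zero and runs are deterministic", {
  dt <- 0.5 * 0.01 / C0
  st <- init_state_1d(64, 0.01, dt)
  st2 <- run_simulation(st, yoshida_coefficients(), 50, boundary = "pec")
  expect_true(all(st2$Ez == 0) && all(st2$Hy == 0))
  a <- run_cavity(300)
  b <- run_cavity(300)
  expect_identical(a$Ez, b$Ez)      # bit-identical repeat runs
  expect_identical(a$Hy, b$Hy)
  expect_error(run_simulation(st, yoshida_coefficients(), 0), "n_steps")
})

test_that("a hard Gaussian pulse translates at the vacuum light speed", {
  delta <- 0.01
  dt <- 0.5 * delta / C0
  n <- 400L
  src <- gaussian_source_spec(1, t0 = 60 * dt, tau = 12 * dt, cell = 100L)
  st <- init_state_1d(n, delta, dt)
  st <- run_simulation(st, yoshida_coefficients(), 400, sources = list(src),
                       boundary = "pec")
  # the rightward peak was emitted at t0; centre = x_s + c0 (t - t0)
  expected_cell <- 100 + (400 - 60) * 0.5
  expect_lt(abs(which.max(st$Ez) - expected_cell), 2)
  expect_gt(max(st$Ez), 0.99)
})

test_that("hard source evaluator follows the closed form", {
  s <- gaussian_source_spec(2, t0 = 1e-9, tau = 2e-10, cell = 10)
  expect_identical(gaussian_hard_source(1e-9, s), 2)
  expect_equal(gaussian_hard_source(1e-9 + 2e-10, s), 2 * exp(-0.5))
  expect_equal(gaussian_hard_source(1e-9 - 2e-10, s), 2 * exp(-0.5))
  expect_lt(gaussian_hard_source(1e-8, s), 1e-100)
  expect_error(gaussian_source_spec(1, 0, -1, 1), "tau")
})

test_that("PEC walls pin Ez to zero and invert reflected pulses", {
  st <- run_cavity(436)
  expect_identical(st$Ez[1], 0)
  expect_identical(st$Ez[length(st$Ez)], 0)
  # after the left-going pulse reflects, a negative peak travels rightward
  st2 <- run_cavity(260) # left pulse (30 cells away) has reflected by now
  expect_lt(min(st2$Ez), -0.9)
})

test_that("cavity mode frequency matches c0 n/(2L) within 1 percent", {
  n <- 120L; delta <- 0.01
  dt <- 0.5 * delta / C0
  L <- n * delta
  k <- 3 * pi / L
  st <- init_state_1d(n, delta, dt)
  xe <- (0:n) * delta
  st$Ez <- sin(k * xe); st$Dz <- st$Ez
  probe <- numeric(4096)
  for (s in seq_along(probe)) {
    st <- advance_step(st, yoshida_coefficients(), boundary = "pec")
    probe[s] <- st$Ez[21]
  }
  nfft <- length(probe)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1)))
  sp <- Mod(fft(probe * hann))[1:(nfft / 2)]
  i0 <- which.max(sp[-1]) + 1L
  # sub-bin peak location by parabolic interpolation on log magnitude
  y <- log(sp[(i0 - 1):(i0 + 1)])
  dshift <- 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3])
  f_peak <- (i0 - 1 + dshift) / (nfft * dt)
  f_mode <- C0 * 3 / (2 * L)
  expect_equal(f_peak, f_mode, tolerance = 0.01)
})

test_that("lossless SFDTD cavity conserves energy; lossy one dissipates", {
  delta <- 0.01; dt <- 0.5 * delta / C0
  src <- gaussian_source_spec(1, t0 = 60 * dt, tau = 12 * dt, cell = 31L)
  st <- init_state_1d(120L, delta, dt)
  en <- numeric(0)
  for (s in 1:3146) {
    st <- advance_step(st, yoshida_coefficients(), list(src), "pec")
    if (s >= 150) en <- c(en, total_energy(st)) # after source release
  }
  drift <- (max(en) - min(en)) / en[1]
  expect_lt(drift, 0.01)                       # < 1% over the long run
  expect_gt(min(en) / en[1], 0.99)             # and no secular decay

  stl <- init_state_1d(120L, delta, dt,
                       vacuum_materials_1d(120L, eps_r = 4, sigma = 0.02))
  enl <- numeric(0)
  for (s in 1:1200) {
    stl <- advance_step(stl, yoshida_coefficients(), list(src), "pec")
    if (s >= 150) enl <- c(enl, total_energy(stl))
  }
  expect_true(all(diff(enl) <= 1e-12 * enl[1])) # non-increasing after switch-off
  expect_lt(enl[length(enl)] / enl[1], 0.1)     # substantial absorption
})

test_that("total_energy matches the quadratic closed forms", {
  st <- init_state_1d(10L, 0.1, 1e-12)
  expect_identical(total_energy(st), 0)
  st$Ez[] <- 2
  expect_equal(total_energy(st), 0.5 * 0.1 * EPS0 * 11 * 4, tolerance = 1e-12)
})

test_that("FDTD(2,2) is exact at the magic time step", {
  delta <- 0.01; n <- 300L
  dt <- delta / C0 # Courant number 1
  # centred source, t0 = 10 tau, long active window: switch-on truncation,
  # release jump and returning reflected tails are all below 1e-14 at the
  # measurement time, so the discrete solution must match the images oracle
  src <- gaussian_source_spec(1, t0 = 120 * dt, tau = 12 * dt, cell = 151L,
                              active_factor = 10)
  st <- init_state_1d(n, delta, dt)
  for (s in 1:260) st <- fdtd22_step(st, list(src), "pec")
  xe <- (0:n) * delta
  exact <- analytic_cavity_waveform(xe, 260 * dt, src, 150 * delta, n * delta,
                                    tail_widths = 12)
  expect_lt(max(abs(st$Ez - exact)), 1e-10)
  # at Courant 0.5 the same pulse disperses: the late peak drops
  dt2 <- 0.5 * delta / C0
  src2 <- gaussian_source_spec(1, t0 = 60 * dt2, tau = 12 * dt2, cell = 80L)
  st2 <- init_state_1d(n, delta, dt2)
  peaks <- numeric(0)
  for (s in 1:560) {
    st2 <- fdtd22_step(st2, list(src2), "pec")
    if (s %in% c(260, 560)) peaks <- c(peaks, max(abs(st2$Ez)))
  }
  expect_lt(peaks[2], peaks[1])
})

test_that("first-order Mur absorbs normally incident pulses", {
  delta <- 0.01; dt <- 0.5 * delta / C0; n <- 400L
  src <- gaussian_source_spec(1, t0 = 60 * dt, tau = 12 * dt, cell = 200L)
  st <- init_state_1d(n, delta, dt)
  incident <- 0
  for (s in 1:1400) {
    st <- advance_step(st, yoshida_coefficients(), list(src), "mur")
    incident <- max(incident, abs(st$Ez[350]))
  }
  expect_gt(incident, 0.99)                 # outgoing pulse passed the probe
  expect_lt(max(abs(st$Ez)) / incident, 0.02) # reflected remnant < 2%
  # PEC comparison: the reflection is total
  st2 <- init_state_1d(n, delta, dt)
  for (s in 1:1400) st2 <- advance_step(st2, yoshida_coefficients(), list(src), "pec")
  expect_gt(max(abs(st2$Ez)), 0.9)
})

test_that("plasma slab transmission matches the transfer-matrix oracle", {
  f <- 2e8; fp <- 1e9; nu <- 2e9
  delta <- 0.002; n <- 1200L
  dt <- 0.5 * delta / C0
  spp <- ceiling(1 / f / dt)
  run_amp <- function(mats) {
    st <- init_state_1d(n, delta, dt, mats)
    src <- sine_soft_source_spec(1e10, f, cell = 200L, ramp_periods = 2)
    vals <- numeric(0)
    nst <- 10L * spp
    for (k in seq_len(nst)) {
      st <- advance_step(st, yoshida_coefficients(), list(src), "mur")
      if (k > nst - spp) vals <- c(vals, st$Ez[800])
    }
    max(abs(vals))
  }
  # each flagged node represents a delta-wide cell, so 51 nodes make a
  # 0.102 m slab; tens of cells per skin depth at these settings
  slab <- 500:550
  t_num <- run_amp(slab_materials_1d(n, slab, fp = fp, nu = nu)) /
    run_amp(vacuum_materials_1d(n))
  t_ana <- Mod(slab_transmission(f, drude_permittivity(f, fp, nu),
                                 length(slab) * delta))
  expect_equal(t_num, t_ana, tolerance = 0.02)
})
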