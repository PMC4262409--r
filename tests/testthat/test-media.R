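test_that("dispersive update reduces to the instantaneous law when lossless", {
  u <- dispersive_e_update(0.5, 0, eps_r = 2, sigma = 0, dt_sub = 1e-12)
  expect_identical(u$E, 0.25)
  expect_identical(u$accum, 0.25)
  expect_error(dispersive_e_update(1, 0, eps_r = 0, sigma = 0, dt_sub = 1), "eps_r")
})

test_that("lossy update follows the closed-form geometric recursion", {
  # with constant flux D the running sum satisfies
  #   S_n - D/q = (S_{n-1} - D/q) * r,  r = eps / (eps + q)
  # so E_n = (q / (eps + q)) * (D/q - S_{n-1}) decays geometrically to 0
  tis <- tissue_table(64e6)$placenta
  dt <- 1e-10
  q <- tis$sigma * dt / physical_constants()$eps0
  r <- tis$eps_r / (tis$eps_r + q)
  D <- 1
  s <- 0
  E_seen <- numeric(40)
  for (n in seq_len(40)) {
    u <- dispersive_e_update(D, s, tis$eps_r, tis$sigma, dt)
    E_seen[n] <- u$E
    s <- u$accum
  }
  E_closed <- (D / (tis$eps_r + q)) * r^(seq_len(40) - 1)
  expect_equal(E_seen, E_closed, tolerance = 1e-12)
  expect_true(all(diff(E_seen) < 0))          # monotone decay towards 0
  expect_true(all(E_seen > 0))

  # switching the drive off: E flips against the accumulated sum and shrinks
  u <- dispersive_e_update(0, s, tis$eps_r, tis$sigma, dt)
  expect_lt(u$E, 0)
  u2 <- dispersive_e_update(0, u$accum, tis$eps_r, tis$sigma, dt)
  expect_lt(abs(u2$E), abs(u$E))
})

test_that("Drude current update matches its ODE limits", {
  expect_identical(drude_current_update(0, 0, 3e9, 10e9, 1e-12), 0)
  eps0 <- physical_constants()$eps0
  # collisionless Taylor limit: J' - J -> eps0 (2 pi fp)^2 E dt
  fp <- 1e9; E <- 2; dt <- 1e-15
  dJ <- drude_current_update(1, E, fp, 1e3, dt) - 1
  expect_equal(dJ, eps0 * (2 * pi * fp)^2 * E * dt, tolerance = 1e-4)
  # fixed point under constant E: J* = eps0 (2 pi fp)^2 E / nu
  # (nu is the Drude collision rate, no 2 pi factor)
  nu <- 5e9
  J <- 0
  for (k in 1:400) J <- drude_current_update(J, E, fp, nu, 2e-11)
  expect_equal(J, eps0 * (2 * pi * fp)^2 * E / nu, tolerance = 1e-6)
})

test_that("time-domain Drude response matches the analytic admittance", {
  # drive the recursion with a sinusoid and least-squares fit the complex
  # phasor; compare with J = eps0 wp^2 / (nu + i w) * E (nu a rate in 1/s)
  eps0 <- physical_constants()$eps0
  fp <- 3e9; nu <- 10e9; f <- 2e8
  dt <- 1 / (f * 400)
  n <- 4000
  tgrid <- (1:n) * dt
  E <- sin(2 * pi * f * tgrid)
  J <- numeric(n)
  for (k in 2:n) J[k] <- drude_current_update(J[k - 1], E[k - 1], fp, nu, dt)
  sel <- tgrid > 3 / f # discard the transient
  fit <- lm(J[sel] ~ 0 + sin(2 * pi * f * tgrid[sel]) + cos(2 * pi * f * tgrid[sel]))
  J_num <- complex(real = coef(fit)[1], imaginary = coef(fit)[2]) # e^{+iwt}
  J_ana <- eps0 * (2 * pi * fp)^2 / complex(real = nu, imaginary = 2 * pi * f)
  expect_equal(Mod(J_num), Mod(J_ana), tolerance = 2e-2)
  # the explicit update lags E by one sample: phase agrees to ~ w dt
  expect_lt(abs(Arg(J_num) - Arg(J_ana)), 2 * pi * f * dt)
})

test_that("Drude permittivity covers the vacuum and shielding regimes", {
  expect_identical(drude_permittivity(1e9, 0, 5e9), 1 + 0i)
  e64 <- drude_permittivity(64e6, 3e9, 10e9)
  expect_lt(Re(e64), 1)           # sub-plasma-frequency regime
  expect_lt(Im(e64), 0)           # lossy (e^{+iwt} convention)
  expect_gt(Mod(e64), 10)         # plasma term dominates far below fp
  expect_error(drude_permittivity(-1, 3e9, 10e9), "f")
})

test_that("passivity: cycle-averaged absorbed power is non-negative", {
  # single-frequency steady drive through the dispersive update
  tis <- tissue_table(128e6)$uterus
  f <- 128e6; dt <- 1 / (f * 200)
  n <- 3000
  s <- 0
  absorbed <- 0
  E_prev <- 0
  for (k in seq_len(n)) {
    D <- tis$eps_r * sin(2 * pi * f * k * dt) # harmonic flux drive
    u <- dispersive_e_update(D, s, tis$eps_r, tis$sigma, dt)
    s <- u$accum
    if (k > n - 200) absorbed <- absorbed + tis$sigma * u$E^2
    E_prev <- u$E
  }
  expect_gt(absorbed, 0)
})
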