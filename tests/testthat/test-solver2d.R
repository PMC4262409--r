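# Two-dimensional drivers: plane-wave injection quality, CFL validation,
# determinism, and field symmetry. Vacuum TF/SF runs use a high frequency so
# a few periods stay cheap; phantom runs use the coarse mini phantom.

tfsf_case <- function(run_fn) {
  nx <- ny <- 80L; delta <- 0.02; f <- 1e9
  dt <- 0.5 * delta / (C0 * sqrt(2))
  spp <- ceiling(1 / f / dt)
  run_fn(nx = nx, ny = ny, delta = delta, frequency = f,
         source = plane_wave_spec(1, f),
         n_steps = 5L * spp, track_start = 4L * spp,
         tf_window = c(20L, 59L, 20L, 59L), boundary = "mur",
         probes = rbind(c(40L, 40L), c(8L, 40L), c(70L, 12L)))
}

test_that("TE plane wave reaches its amplitude inside the window and leaks below 1 percent", {
  r <- tfsf_case(run_te2d)
  spp <- ceiling(1 / 1e9 / r$grid$dt)
  amp <- max(abs(r$probes[(4 * spp):(5 * spp), 1]))
  expect_equal(amp, 1, tolerance = 0.01)
  expect_lt(max(abs(r$probes[, 2])), 0.01) # scattered region, left of window
  expect_lt(max(abs(r$probes[, 3])), 0.01) # scattered region, below window
  # zero-amplitude source leaves the state identically zero
  r0 <- run_te2d(nx = 40L, ny = 40L, delta = 0.02, frequency = 1e9,
                 source = plane_wave_spec(0, 1e9), n_steps = 50,
                 tf_window = c(10L, 29L, 10L, 29L))
  expect_true(all(r0$Ey == 0) && all(r0$Hz == 0))
})

test_that("TM plane wave reaches its amplitude inside the window and leaks below 1 percent", {
  r <- tfsf_case(run_tm2d)
  spp <- ceiling(1 / 1e9 / r$grid$dt)
  amp <- max(abs(r$probes[(4 * spp):(5 * spp), 1]))
  expect_equal(amp, 1, tolerance = 0.01)
  expect_lt(max(abs(r$probes[, 2])), 0.01)
  expect_lt(max(abs(r$probes[, 3])), 0.01)
})

test_that("grid_spec rejects time steps beyond the scheme limit", {
  expect_s3_class(grid_spec(2, c(50, 50), 0.01, courant = 0.5), "grid_spec")
  expect_error(grid_spec(2, c(50, 50), 0.01, courant = 0.7), "CFL")
  expect_error(grid_spec(1, 120, 0.01, courant = 0.9), "CFL") # sfdtd 1-D limit 0.674
  # the classic scheme admits the magic time step
  lf <- leapfrog_coefficients()
  expect_s3_class(grid_spec(1, 120, 0.01, courant = 1, coeffs = lf,
                            a1 = 1, a2 = 0), "grid_spec")
})

test_that("identical 2-D configurations give bit-identical results", {
  spec <- mini_phantom(60)
  f <- 64e6
  run_once <- function() {
    run_tm2d(phantom = spec, frequency = f, source = plane_wave_spec(1, f),
             n_steps = 300, track_start = 100)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$Ez, b$Ez)
  expect_identical(a$peak_ez, b$peak_ez)
})

test_that("symmetric phantom under axis-aligned incidence gives mirror-symmetric fields", {
  spec <- mini_phantom(60)
  f <- 64e6
  r <- run_tm2d(phantom = spec, frequency = f, source = plane_wave_spec(1, f),
                n_steps = 600, track_start = 500)
  ny <- spec$ny
  expect_lt(max(abs(r$Ez - r$Ez[, (ny + 1):1])) / max(abs(r$Ez)), 1e-12)
  rte <- run_te2d(phantom = spec, frequency = f, source = plane_wave_spec(1, f),
                  n_steps = 600, track_start = 500)
  expect_lt(max(abs(rte$Ey - rte$Ey[, ny:1])) / max(abs(rte$Ey)), 1e-12)
  expect_lt(max(abs(rte$Ex + rte$Ex[, (ny + 1):1])) / max(abs(rte$Ex)), 1e-12)
})
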