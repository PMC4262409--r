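test_that("SAR arithmetic follows sigma |E|^2 / (2 rho) on tissue cells only", {
  spec <- phantom_spec(nx = 51L, ny = 51L, delta = 1.6e-2)
  mm <- build_phantom(spec, 64e6)
  pk1 <- matrix(1, 51, 51)
  pk0 <- matrix(0, 51, 51)
  sm <- compute_sar(pk1, pk0, mm)
  centre <- c(26L, 26L)
  # fetus cell, unit peak Ex: 0.39 / (2 * 987)
  expect_equal(sm$sar[centre[1], centre[2]], 0.39 / (2 * 987), tolerance = 1e-12)
  expect_true(all(sm$sar[mm$kind == "vacuum"] == 0))
  expect_true(all(sm$sar >= 0))
  # quadratic scaling: doubling both peaks quadruples SAR
  sm2 <- compute_sar(2 * pk1, pk0, mm)
  expect_equal(sm2$sar, 4 * sm$sar, tolerance = 1e-12)
  # profile peaks equal the maxima of their arrays
  expect_identical(sm$peak_sarx, max(sm$sar_x_profile))
  expect_identical(sm$peak_sary, max(sm$sar_y_profile))
  expect_identical(sm$peak_sar, max(sm$sar))
  expect_error(compute_sar(pk1[1:10, 1:10], pk0[1:10, 1:10], mm), "match")
})

test_that("reduction_percent follows its closed form", {
  expect_identical(reduction_percent(0.5, 0.5), 0)
  expect_identical(reduction_percent(0.5, 0), 100)
  expect_equal(reduction_percent(0.88, 0.78), 100 * 0.10 / 0.88,
               tolerance = 1e-12)
  expect_error(reduction_percent(0, 1), "peak_without")
})

test_that("tracked peaks recover a steady sinusoidal amplitude", {
  nx <- ny <- 60L; delta <- 0.02; f <- 1e9
  dt <- 0.5 * delta / (C0 * sqrt(2))
  spp <- ceiling(1 / f / dt) # >> 20 samples per period
  tw <- c(15L, 44L, 15L, 44L)
  r1 <- run_tm2d(nx = nx, ny = ny, delta = delta, frequency = f,
                 source = plane_wave_spec(1, f), n_steps = 4L * spp,
                 track_start = 3L * spp, tf_window = tw)
  inner <- r1$peak_ez[25:35, 25:35]
  expect_equal(max(inner), 1, tolerance = 0.01)
  # steady state: doubling the tracking window leaves the peaks unchanged
  r2 <- run_tm2d(nx = nx, ny = ny, delta = delta, frequency = f,
                 source = plane_wave_spec(1, f), n_steps = 5L * spp,
                 track_start = 3L * spp, tf_window = tw)
  expect_equal(max(r2$peak_ez[25:35, 25:35]), max(inner), tolerance = 0.01)
  # a window shorter than one period is flagged
  r3 <- run_tm2d(nx = nx, ny = ny, delta = delta, frequency = f,
                 source = plane_wave_spec(1, f), n_steps = 3L * spp + 10L,
                 track_start = 3L * spp, tf_window = tw)
  expect_warning(track_peaks(r3), "shorter than one source period")
})

test_that("SAR maps inherit mirror symmetry and the shielding is passive", {
  s0 <- mini_sar_cached(0)
  s60 <- mini_sar_cached(60)
  s90 <- mini_sar_cached(90)
  for (sm in list(s0, s60, s90)) {
    ny <- ncol(sm$sar)
    expect_lt(max(abs(sm$sar - sm$sar[, ny:1])) / max(sm$sar), 1e-10)
  }
  # shielding never increases the axis-profile peaks (f << fp)
  expect_lte(s60$peak_sarx, s0$peak_sarx)
  expect_lte(s60$peak_sary, s0$peak_sary)
  expect_lte(s90$peak_sarx, s0$peak_sarx)
  expect_lte(s90$peak_sary, s0$peak_sary)
  # widening the arc from 60 to 90 degrees helps further
  expect_lte(s90$peak_sarx, s60$peak_sarx)
})
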