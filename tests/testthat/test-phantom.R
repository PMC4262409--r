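test_that("tissue table returns the tabulated dielectric properties", {
  t64 <- tissue_table(64e6)
  expect_equal(t64$uterus, list(eps_r = 92.19, sigma = 0.91, rho = 1052))
  expect_equal(t64$fetus, list(eps_r = 42.68, sigma = 0.39, rho = 987))
  t128 <- tissue_table(128e6)
  expect_equal(t128$placenta, list(eps_r = 73.19, sigma = 1.00, rho = 1058))
  expect_equal(t128$fetus$sigma, 0.412)
  expect_error(tissue_table(1e9), "unsupported")
})

test_that("phantom geometry validation rejects malformed specs", {
  expect_error(phantom_spec(r_fetus = 0.2), "nested")
  expect_error(phantom_spec(layer_inner_radius = 0.1), "overlap")
  expect_error(phantom_spec(layer_angle = 360), "layer_angle")
  expect_error(phantom_spec(nx = 50, ny = 50, delta = 2e-3), "exceeds the grid")
})

test_that("material map classifies nested discs with the right properties", {
  spec <- phantom_spec(nx = 101L, ny = 101L, delta = 8e-3, layer_angle = 60)
  mm <- build_phantom(spec, 64e6)
  t64 <- tissue_table(64e6)
  centre <- c(51, 51)
  expect_identical(mm$kind[centre[1], centre[2]], "fetus")
  expect_equal(mm$eps_r[centre[1], centre[2]], t64$fetus$eps_r)
  expect_equal(mm$rho[centre[1], centre[2]], t64$fetus$rho)
  # vacuum cells: eps 1, sigma 0; plasma cells carry eps_r 1 (ADE current)
  expect_true(all(mm$eps_r[mm$kind == "vacuum"] == 1))
  expect_true(all(mm$sigma[mm$kind == "vacuum"] == 0))
  expect_true(all(mm$eps_r[mm$kind == "plasma"] == 1))
  expect_true(any(mm$kind == "plasma"))
  # zero angle: no plasma, map identical to the unshielded phantom
  mm0 <- build_phantom(phantom_spec(nx = 101L, ny = 101L, delta = 8e-3,
                                    layer_angle = 0), 64e6)
  expect_false(any(mm0$kind == "plasma"))
  keep <- mm$kind != "plasma" # same mask on both sides
  expect_identical(mm0$eps_r[keep], mm$eps_r[keep])
})

test_that("disc areas match the analytic circle area within 2 percent", {
  # full-resolution grid: r_fetus = 50 cells
  spec <- phantom_spec(nx = 450L, ny = 450L, delta = 2e-3)
  mm <- build_phantom(spec, 64e6)
  n_fetus <- sum(mm$kind == "fetus")
  expect_equal(n_fetus * spec$delta^2, pi * spec$r_fetus^2, tolerance = 0.02)
  n_ut <- sum(mm$kind %in% c("uterus", "placenta", "fetus"))
  expect_equal(n_ut * spec$delta^2, pi * spec$r_uterus^2, tolerance = 0.02)
})

test_that("material maps are exactly mirror symmetric and angle-monotone", {
  for (ny in c(100L, 101L)) { # even and odd grids
    spec <- phantom_spec(nx = 101L, ny = ny, delta = 8e-3, layer_angle = 90)
    mm <- build_phantom(spec, 64e6)
    expect_identical(mm$kind, mm$kind[, ny:1])
    expect_identical(mm$sigma, mm$sigma[, ny:1])
  }
  counts <- vapply(c(0, 60, 90, 120, 180), function(a) {
    sum(build_phantom(phantom_spec(nx = 101L, ny = 101L, delta = 8e-3,
                                   layer_angle = a), 64e6)$kind == "plasma")
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})
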