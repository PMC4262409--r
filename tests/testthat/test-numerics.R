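test_that("Yoshida composition satisfies the closed-form identities", {
  co <- yoshida_coefficients()
  # independent evaluation of the triple-jump weights
  w1 <- 1 / (2 - 2^(1 / 3))
  w0 <- 1 - 2 * w1
  expect_equal(w1, 1.35120719195966, tolerance = 1e-12)
  expect_equal(w0, -1.70241438391932, tolerance = 1e-12)
  expect_identical(co$m, 4L)
  expect_identical(co$p, 4L)
  expect_equal(sum(co$c), 1, tolerance = 1e-14)
  expect_equal(sum(co$d), 1, tolerance = 1e-14)
  expect_equal(co$c, rev(co$c))                      # palindromic
  expect_identical(co$d[co$m], 0)                    # trailing zero H stage
  expect_equal(co$d[1], w1, tolerance = 1e-14)
  expect_equal(co$d[2], w0, tolerance = 1e-14)
  expect_equal(co$c[2], (w1 + w0) / 2, tolerance = 1e-14)
})

test_that("stage-coefficient validation enforces sums and symmetry", {
  # valid: 1-stage first-order split and the Strang leapfrog
  expect_s3_class(load_stage_coefficients(1, 1, p = 1), "stage_coefficients")
  lf <- load_stage_coefficients(c(0.5, 0.5), c(1, 0), p = 2)
  expect_identical(lf$m, 2L)
  # invalid: sums off beyond 1e-12, broken symmetry, length mismatch
  expect_error(load_stage_coefficients(c(0.45, 0.45), c(1, 0), p = 2), "sum")
  expect_error(load_stage_coefficients(c(0.5, 0.5), c(0.9, 0.1), p = 2),
               "symmetry|d\\[m\\]")
  expect_error(load_stage_coefficients(c(0.3, 0.7), c(1, 0), p = 2),
               "palindromic")
  expect_error(load_stage_coefficients(c(1, 0), 1, p = 1), "length")
})

test_that("stability intervals match the classical values", {
  expect_equal(stage_stability_limit(leapfrog_coefficients()), 2,
               tolerance = 1e-3)
  # Yoshida 4th-order composition has a reduced interval (~1.573)
  xy <- stage_stability_limit(yoshida_coefficients())
  expect_gt(xy, 1.5)
  expect_lt(xy, 1.7)
  # fourth-order staggered symbol peaks at 7/3; classic two-point at 2
  expect_equal(sfdtd:::stencil_symbol_max(9 / 8, -1 / 24), 7 / 3,
               tolerance = 1e-6)
  expect_equal(sfdtd:::stencil_symbol_max(1, 0), 2, tolerance = 1e-9)
  # magic-time-step limit for the classic scheme in 1-D
  expect_equal(cfl_limit(leapfrog_coefficients(), 1, 1, 0), 1,
               tolerance = 1e-3)
})

test_that("staggered_diff4 is exact on polynomials up to cubic", {
  x <- seq(0, 11)
  h <- 0.37
  xs <- x * h
  for (p in 0:3) {
    d <- staggered_diff4(xs^p, h)
    mid <- (xs[-length(xs)] + xs[-1]) / 2
    interior <- 2:(length(d) - 1)
    expected <- if (p == 0) rep(0, length(mid)) else p * mid^(p - 1)
    expect_equal(d[interior], expected[interior], tolerance = 1e-12)
  }
  expect_error(staggered_diff4(c(1, 2, 3), 1), "length")
  expect_error(staggered_diff4(1:10, -1), "positive")
})

test_that("staggered_diff4 error on sin(kx) shrinks at fourth order", {
  k <- 1
  errs <- vapply(c(20, 40, 80), function(n) {
    h <- 2 * pi / n
    x <- seq(0, 2 * pi, by = h)
    d <- staggered_diff4(sin(k * x), h)
    mid <- (x[-length(x)] + x[-1]) / 2
    interior <- 3:(length(d) - 2)
    max(abs(d[interior] - k * cos(k * mid[interior])))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 3.5))
})

test_that("fitted temporal orders match composition theory", {
  expect_error(empirical_order(yoshida_coefficients(), 2), ">= 3")
  o2 <- empirical_order(leapfrog_coefficients(), 4)
  expect_gt(o2, 1.8); expect_lt(o2, 2.2)
  o4 <- empirical_order(yoshida_coefficients(), 4)
  expect_gt(o4, 3.5); expect_lt(o4, 4.5)
})
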