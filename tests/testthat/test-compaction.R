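# Material-model operations: frozen hand-derived values, pure-substance
# degeneracy, and property checks against independent oracles.

kw150 <- kawakita_coefficients(1.22954, 0.4981, 0.0072)
kw60 <- kawakita_coefficients(1.62302, 0.4891, 0.0041)
kwl <- list(A150 = kw150, A60 = kw60)
strength <- strength_mix_coefficients(19.99, 5.56, 28.32, 3.80, 15.09)

test_that("mix_bulk_density is the mass-weighted harmonic mean", {
  pure <- blend_composition("A150", fraction = 1)
  expect_equal(mix_bulk_density(pure, c(A150 = 0.73)), 0.73)
  b <- blend_composition(c("A150", "A60"), fraction = c(0.5, 0.5))
  expect_equal(mix_bulk_density(b, c(A150 = 0.73, A60 = 1.41)),
               0.961962616822, tolerance = 1e-9)
  # constant-density invariance and bounds
  for (x in c(0.2, 0.5, 0.9)) {
    bx <- blend_composition(c("A150", "A60"), fraction = c(x, 1 - x))
    expect_equal(mix_bulk_density(bx, c(A150 = 1.1, A60 = 1.1)), 1.1)
    m <- mix_bulk_density(bx, c(A150 = 0.73, A60 = 1.41))
    expect_gt(m, 0.73); expect_lt(m, 1.41)
  }
  expect_error(mix_bulk_density(b, c(A150 = 0.73, A60 = 0)), "> 0")
  expect_error(mix_bulk_density(b, c(A150 = 0.73)), "unknown material")
})

test_that("tablet weight and in-die density are a consistent inverse pair", {
  expect_equal(tablet_weight(11.28, 7, 0.73), 0.510656636992, tolerance = 1e-10)
  expect_equal(tablet_weight(11.28, 7, 1.41), 0.986336791999, tolerance = 1e-10)
  expect_error(tablet_weight(11.28, 7, 0), "> 0")
  expect_error(in_die_density(0.5, 11.28, 0), "> 0")
  # exact closed form: rho scales with h_dos / h
  expect_equal(in_die_density(tablet_weight(11.28, 7, 0.73), 11.28, 3.2),
               0.73 * 7 / 3.2, tolerance = 1e-12)
  # round trip at h = h_dos returns the fill density; halving h doubles rho
  m <- tablet_weight(11.28, 7, 0.95)
  expect_equal(in_die_density(m, 11.28, 7), 0.95, tolerance = 1e-12)
  expect_equal(in_die_density(m, 11.28, 3.5),
               2 * in_die_density(m, 11.28, 7), tolerance = 1e-12)
})

test_that("the Kawakita mixture density has the right limits and monotonicity", {
  pure <- blend_composition("A150", fraction = 1)
  expect_equal(kawakita_mixture_density(100, pure, kwl), 1.55344388879,
               tolerance = 1e-9)
  expect_equal(kawakita_mixture_density(0, pure, kwl,
                                        low_pressure_warning = FALSE),
               1.22954, tolerance = 1e-12)
  # analytic asymptote approached from below, never reached
  expect_equal(kawakita_asymptote(kw150), 2.44977087069, tolerance = 1e-9)
  expect_lt(kawakita_mixture_density(1e6, pure, kwl), kawakita_asymptote(kw150))
  expect_lt(kawakita_asymptote(kw150), 2.842)
  # strict monotonicity in P for several blends
  for (x in c(0, 0.3, 0.7, 1)) {
    rho <- kawakita_mixture_density(seq(20, 400, by = 20), a60_blend(x), kwl)
    expect_true(all(diff(rho) > 0))
  }
  # pure-substance reduction at x_i = 1 is exact
  almost <- blend_composition(c("A150", "A60"), fraction = c(1, 0))
  expect_identical(kawakita_mixture_density(150, almost, kwl),
                   kawakita_mixture_density(150, pure, kwl))
  expect_warning(kawakita_mixture_density(10, pure, kwl), "below 20 MPa")
})

test_that("stress inversion matches the bisection oracle over a composition grid", {
  pure <- blend_composition("A150", fraction = 1)
  expect_equal(invert_compression_stress(1.598, pure, kwl),
               bisect_invert(1.598, pure, kwl), tolerance = 1e-8)
  # forward-inverse round trip
  b <- blend_composition(c("A150", "A60"), fraction = c(0.5, 0.5))
  expect_equal(invert_compression_stress(
    kawakita_mixture_density(200, b, kwl), b, kwl), 200, tolerance = 1e-9)
  # 5 compositions x 20 stresses
  for (x in c(0, 0.25, 0.5, 0.75, 1)) {
    comp <- a60_blend(x)
    for (P in seq(20, 400, length.out = 20)) {
      rho <- kawakita_mixture_density(P, comp, kwl)
      expect_equal(invert_compression_stress(rho, comp, kwl),
                   bisect_invert(rho, comp, kwl), tolerance = 1e-6)
    }
  }
  # three components fall back to numeric root finding
  k3 <- c(kwl, list(C = kawakita_coefficients(1.0, 0.4, 0.01)))
  b3 <- blend_composition(c("A150", "A60", "C"), fraction = c(0.4, 0.4, 0.2))
  rho3 <- kawakita_mixture_density(120, b3, k3)
  expect_equal(invert_compression_stress(rho3, b3, k3), 120, tolerance = 1e-6)
  # unreachable densities are rejected on both sides
  expect_error(invert_compression_stress(1.0, pure, kwl), "unreachable")
  expect_error(invert_compression_stress(2.6, pure, kwl), "unreachable")
})

test_that("out-die density follows the two-point recovery line", {
  pure <- blend_composition("A150", fraction = 1)
  # synthetic calibration built to give exactly d_in = 0.001 P, d_slow = 0.02
  rc <- recovery_calibration(30, 400,
                             rho_P_max = c(1.45, 2.20),
                             rho_P_0 = c(1.45 - 0.03, 2.20 - 0.40),
                             rho_out_die = c(1.40, 1.78))
  rcl <- list(A150 = rc, A60 = rc)
  expect_equal(out_die_density(150, 1.7, pure, rcl),
               1.7 - 0.001 * 150 - 0.02, tolerance = 1e-12)
  # no recovery at all: rho_P_max unchanged
  rc0 <- recovery_calibration(30, 400, c(1.45, 2.2), c(1.45, 2.2), c(1.45, 2.2))
  expect_equal(out_die_density(150, 1.7, pure, list(A150 = rc0)), 1.7)
  expect_lte(out_die_density(150, 1.7, pure, rcl), 1.7)
  # pure material reproduces the pure-substance line through a blend carrying
  # a zero fraction of the other component
  almost <- blend_composition(c("A150", "A60"), fraction = c(1, 0))
  expect_equal(out_die_density(90, 1.6, almost, rcl),
               out_die_density(90, 1.6, pure, rcl), tolerance = 1e-12)
  expect_error(out_die_density(150, 0.1, pure, rcl), "not positive")
})

test_that("out-die porosity uses the volume-additive mixture solid density", {
  pure <- blend_composition("A150", fraction = 1)
  sol <- c(A150 = 2.842, A60 = 2.849)
  expect_equal(out_die_porosity(1.421, pure, sol), 0.5, tolerance = 1e-12)
  expect_equal(out_die_porosity(2.842, pure, sol), 0)
  b <- blend_composition(c("A150", "A60"), fraction = c(0.5, 0.5))
  # implied mixture solid density: harmonic mean 2.845496
  eps <- out_die_porosity(1.5, b, sol)
  expect_equal(1.5 / (1 - eps), 2.84549569496, tolerance = 1e-9)
  expect_error(out_die_porosity(2.9, b, sol), "exceeds")
})

test_that("strength mixing rule evaluates and stays monotone", {
  expect_equal(sigma0_of_x(0, strength), 48.31)
  expect_equal(sigma0_of_x(1, strength), 5222.1784981, tolerance = 1e-8)
  expect_equal(kb_of_x(c(0, 0.5, 1), strength), c(15.09, 16.99, 18.89))
  xg <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sigma0_of_x(xg, strength)) > 0))
  expect_error(sigma0_of_x(1.2, strength), "\\[0, 1\\]")
  expect_error(kb_of_x(-0.1, strength), "\\[0, 1\\]")
})

test_that("tensile strength decays exponentially with porosity", {
  expect_equal(tensile_strength(0, 0.37, strength),
               sigma0_of_x(0.37, strength))
  expect_equal(tensile_strength(0.49, 1, strength), 0.498859857492,
               tolerance = 1e-9)
  # log-linearity identity
  e1 <- 0.2; e2 <- 0.45; x <- 0.6
  expect_equal(log(tensile_strength(e1, x, strength)) -
                 log(tensile_strength(e2, x, strength)),
               -kb_of_x(x, strength) * (e1 - e2), tolerance = 1e-12)
  # strictly decreasing in porosity, increasing in x at fixed porosity
  eg <- seq(0.05, 0.6, by = 0.05)
  expect_true(all(diff(tensile_strength(eg, 0.5, strength)) < 0))
  xg <- seq(0, 1, by = 0.1)
  expect_true(all(diff(tensile_strength(0.3, xg, strength)) > 0))
  expect_error(tensile_strength(1, 0.5, strength), "porosity")
})
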