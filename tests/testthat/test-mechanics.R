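# tensile metrics, Hertz model and point stiffness

test_that("tensile metrics recover a linear-elastic curve exactly", {
  eps <- seq(0, 0.01, length.out = 101)
  cv <- tensile_curve(eps, 1e9 * eps)
  tm <- tensile_metrics(cv)
  expect_equal(tm$modulus, 1e9, tolerance = 1e-12)
  expect_equal(tm$fracture_stress, 1e7)
  expect_equal(tm$fracture_strain, 0.01)
  # triangle to 10 MPa at 1% strain: work of rupture 0.05 MJ/m^3
  cv2 <- tensile_curve(seq(0, 0.01, length.out = 501),
                       1e9 * seq(0, 0.01, length.out = 501))
  tm2 <- tensile_metrics(cv2)
  expect_equal(tm2$work_of_rupture, 0.5 * 1e7 * 0.01, tolerance = 1e-6)
  expect_equal(tm2$work_of_rupture, 0.05e6, tolerance = 1e-6)
})

test_that("fracture stress is the curve maximum and inputs are validated", {
  eps <- seq(0, 0.02, length.out = 200)
  sig <- 1e9 * eps; sig[eps > 0.01] <- 1e7 * (1 - (eps[eps > 0.01] - 0.01) * 50)
  tm <- tensile_metrics(tensile_curve(eps, sig))
  expect_equal(tm$fracture_stress, max(sig))
  expect_error(tensile_curve(c(0, 2e-4, 1e-4), c(0, 1, 2)), "non-decreasing")
  expect_error(tensile_metrics(tensile_curve(c(0, 0.01), c(0, 1))), "window")
})

test_that("tensile modulus is invariant to uniform resampling", {
  f <- function(n) {
    eps <- seq(0, 0.01, length.out = n)
    tensile_metrics(tensile_curve(eps, 2.5e9 * eps))$modulus
  }
  expect_equal(f(51), f(501), tolerance = 1e-9)
})

test_that("the Hertz force has its closed forms and shape", {
  expect_equal(hertz_force(1, 0, 1, 0), 0)
  expect_equal(hertz_force(1, 0, 1, 1), 4 / 3)
  expect_equal(hertz_force(1, 0, 1, 4), 32 / 3)
  expect_error(hertz_force(1, 0.3, 1, -1), "negative")
  # strictly increasing and convex in delta
  d <- seq(0, 5, length.out = 100)
  F <- hertz_force(2e9, 0.3, 10e-9, d)
  expect_true(all(diff(F) > 0))
  expect_true(all(diff(diff(F)) > 0))
})

test_that("hertz_fit inverts the forward model", {
  g <- gen_indent_curve(E = 1e9, nu = 0.3, R_tip = 10e-9, noise_frac = 0, seed = 1)
  fit <- hertz_fit(g$curve)
  expect_lt(abs(fit$E - 1e9) / 1e9, 1e-3)
  expect_lt(abs(fit$z0 - g$truth$z0), 2e-10)
  # across moduli, robust and plain loss
  for (E in c(1e8, 5e9, 4e10)) {
    gg <- gen_indent_curve(E = E, noise_frac = 0, seed = 2)
    expect_lt(abs(hertz_fit(gg$curve)$E - E) / E, 1e-3)
    expect_lt(abs(hertz_fit(gg$curve, robust = FALSE)$E - E) / E, 1e-3)
  }
  expect_error(hertz_fit(force_curve(seq(0, 1e-8, length.out = 50),
                                     rep(0, 50))), "zero")
})

test_that("noisy Hertz curves recover the modulus to a few percent", {
  errs <- vapply(1:20, function(k) {
    E <- 10^runif(1, 8, 10.5)
    g <- gen_indent_curve(E = E, noise_frac = 0.01, seed = 1000 + k)
    abs(hertz_fit(g$curve)$E - E) / E
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("point stiffness is force over corrected deformation", {
  # synthetic linear-elastic sample: F = k_s * delta_s, measured z
  # includes the cantilever deflection F / k_c
  k_s <- 20; k_c <- 200; z0 <- 1e-8
  F <- seq(0, 800e-9, length.out = 200)
  z <- z0 + F / k_s + F / k_c
  cv <- force_curve(z, F, k_c = k_c)
  expect_equal(point_stiffness(cv, z0 = z0), k_s, tolerance = 1e-9)
  # 800 nN over 40 nm -> 20 N/m
  expect_equal(800e-9 / 40e-9, 20)
  expect_equal(point_stiffness(cv, z0 = z0, method = "slope"), k_s,
               tolerance = 1e-6)
  # rigid sample: deformation -> 0 is an error
  z_rigid <- z0 + F / k_c
  expect_error(point_stiffness(force_curve(z_rigid, F, k_c = k_c), z0 = z0),
               "deformation")
  # linear-elastic synthetic curve recovers the spring constant via the
  # fitted contact point too (within a few percent)
  g <- gen_indent_curve(E = 2e9, noise_frac = 0, seed = 3)
  ps <- point_stiffness(g$curve)
  expect_lt(abs(ps - g$truth$stiffness) / g$truth$stiffness, 0.35)
})
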