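test_that("cap geometry reproduces the flat-disc, hemisphere and full-bud limits", {
  A <- 31415.9
  flat <- cap_from(A, 0)
  expect_equal(flat$A_p, A)
  expect_equal(flat$dA_excess, 0)
  expect_equal(flat$D_proj, 2 * sqrt(A / pi))
  expect_true(is.na(flat$R))

  hemi <- cap_from(4 * pi * 50^2, 1)
  expect_equal(hemi$R, sqrt(4 * pi * 50^2 / (2 * pi)), tolerance = 1e-12)
  expect_equal(hemi$psi, pi / 2)

  bud <- cap_from(A, 2)
  expect_equal(bud$A_p, 0)
  expect_equal(bud$D_proj, 0)
  expect_equal(bud$rim_len, 0)

  expect_error(cap_from(-1, 1), "A_d")
  expect_error(cap_from(100, 2.1), "u")
})

test_that("projected plus excess area equals the coat area for random shapes", {
  set.seed(11)
  for (i in 1:200) {
    A <- 10^runif(1, 3, 6)
    u <- runif(1, 0, 2)
    s <- cap_from(A, u)
    expect_identical(s$A_p + s$dA_excess, A)  # exact conservation
    expect_equal(s$rim_len, pi * s$D_proj, tolerance = 1e-12)
    expect_equal(s$D_proj, 2 * sqrt(A * (2 - u) / (2 * pi)),
                 tolerance = 1e-12)
  }
})

test_that("mechanical energy matches a term-by-term quadrature oracle", {
  coat <- coat_params("test", kappa_c = 20, c0 = 1 / 50, lambda_rim = 0,
                      a_p = 25)
  A <- 31416
  E_formula <- mech_energy(cap_from(A, 1), coat, 0.01)
  E_quad <- energy_quadrature(A, 1, coat, 0.01)
  expect_equal(E_formula, E_quad, tolerance = 1e-9)

  set.seed(7)
  for (i in 1:5) {
    coat_i <- coat_params("r", kappa_c = runif(1, 10, 40),
                          c0 = 1 / runif(1, 40, 300),
                          lambda_rim = runif(1, 0, 0.5), a_p = 25)
    A <- 10^runif(1, 3.5, 5.5); u <- runif(1, 0.05, 1.95)
    s <- runif(1, 0, 0.05)
    expect_equal(mech_energy(cap_from(A, u), coat_i, s),
                 energy_quadrature(A, u, coat_i, s), tolerance = 1e-9)
  }
})

test_that("energy limits: relieved curvature gives zero, flat coat is frustrated", {
  coat <- coat_params("t", kappa_c = 20, c0 = 1 / 50, lambda_rim = 0,
                      a_p = 25)
  # a cap whose radius equals 1/c0: u such that sqrt(2 pi u / A) = c0
  A <- 2e4
  u <- coat$c0^2 * A / (2 * pi)
  expect_equal(1 / cap_from(A, u)$R, coat$c0, tolerance = 1e-12)
  expect_equal(mech_energy(cap_from(A, u), coat, 0), 0, tolerance = 1e-9)
  # flat limit
  expect_equal(mech_energy(cap_from(A, 0), coat, 0.3),
               2 * coat$kappa_c * A * coat$c0^2, tolerance = 1e-12)
})

test_that("tension derivative of the energy is the stored excess area", {
  coat <- coat_preset("cav1")
  s <- cap_from(2e5, 0.8)
  h <- 1e-6
  dEds <- (mech_energy(s, coat, 0.01 + h) - mech_energy(s, coat, 0.01 - h)) /
    (2 * h)
  expect_equal(dEds, s$dA_excess, tolerance = 1e-6)
  expect_gt(mech_energy(s, coat, 0.02), mech_energy(s, coat, 0.01))
})

test_that("closed-form optimal cap depth matches a numeric minimizer", {
  coat0 <- function(kappa, c0) coat_params("t", kappa_c = kappa, c0 = c0,
                                           lambda_rim = 0, a_p = 25)
  # exact full bud at the preferred bud area
  c0 <- 1 / 80
  cf <- optimal_angle_closed_form(4 * pi / c0^2, coat0(20, c0), 0)
  expect_identical(cf$u_star, 2)
  # documented shallow-cap example
  cf2 <- optimal_angle_closed_form(2e5, coat0(20, 1 / 200), 0)
  expect_equal(cf2$u_star, (1 / 200)^2 * 2e5 / (2 * pi), tolerance = 1e-12)
  expect_lt(acos(1 - cf2$u_star) * 180 / pi, 90)
  expect_equal(acos(1 - cf2$u_star) * 180 / pi, 78, tolerance = 0.01)
  expect_equal(cap_from(2e5, cf2$u_star)$D_proj, 390, tolerance = 0.01)
  # no spontaneous curvature: flat wins
  expect_identical(optimal_angle_closed_form(1e5, coat0(20, 0), 0.01)$u_star, 0)
  # rejects rim-bearing coats
  expect_error(optimal_angle_closed_form(1e5, coat_preset("cav1"), 0),
               "lambda_rim")

  set.seed(3)
  for (i in 1:25) {
    kappa <- runif(1, 10, 40)
    c0 <- 1 / runif(1, 60, 300)
    A <- runif(1, 1e4, min(1.6 * pi / c0^2, 5e5))
    s <- runif(1, 0, 0.05)
    coat <- coat0(kappa, c0)
    cf <- optimal_angle_closed_form(A, coat, s)
    expect_lt(abs(cf$u_star - numeric_u_star(A, coat, s)), 1e-6)
    expect_equal(cf$E_star, mech_energy(cap_from(A, cf$u_star), coat, s),
                 tolerance = 1e-10)
  }
})

test_that("optimal depth is monotone: down in tension, up in spontaneous curvature", {
  A <- 2e5
  sig <- seq(0, 0.05, length.out = 20)
  u_sig <- vapply(sig, function(s)
    optimal_angle_closed_form(A, coat_params("t", 20, 1 / 200, 0, 25),
                              s)$u_star, numeric(1))
  expect_true(all(diff(u_sig) <= 0))
  c0s <- seq(1 / 500, 1 / 120, length.out = 20)
  u_c0 <- vapply(c0s, function(c0)
    optimal_angle_closed_form(A, coat_params("t", 20, c0, 0, 25),
                              0.002)$u_star, numeric(1))
  expect_true(all(diff(u_c0) >= 0))
})

test_that("tension unit conversion matches kBT at room temperature and round-trips", {
  expect_equal(convert_tension(1, "kBT_per_nm2", "mN_per_m"), 4.1164,
               tolerance = 1e-4)
  expect_identical(convert_tension(0, "mN_per_m", "kBT_per_nm2"), 0)
  expect_equal(convert_tension(1, "pN_per_nm", "mN_per_m"), 1)
  set.seed(5)
  for (x in runif(5, 0, 10)) {
    y <- convert_tension(x, "kBT_per_nm2", "mN_per_m", 310)
    expect_equal(convert_tension(y, "mN_per_m", "kBT_per_nm2", 310), x,
                 tolerance = 1e-12)
  }
  expect_error(convert_tension(1, "dyn_per_cm", "mN_per_m"), "unknown unit")
})

test_that("coat presets carry the published spontaneous curvatures", {
  expect_identical(coat_preset("cav1")$c0, 1 / 200)
  expect_identical(coat_preset("ptrf")$c0, 1 / 50)
  expect_error(coat_params("x", kappa_c = -1, c0 = 0, lambda_rim = 0,
                           a_p = 25), "kappa_c")
})

test_that("coat parameters load from YAML config with preset overrides", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("preset: ptrf", "kappa_c: 30"), cfg)
  coat <- coat_params_from_config(cfg)
  expect_identical(coat$c0, 1 / 50)
  expect_identical(coat$kappa_c, 30)
  cfg2 <- tempfile(fileext = ".yaml")
  writeLines(c("name: custom", "kappa_c: 15", "c0: 0.004",
               "lambda_rim: 0", "a_p: 30"), cfg2)
  expect_identical(coat_params_from_config(cfg2)$a_p, 30)
})
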