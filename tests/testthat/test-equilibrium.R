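test_that("se_model has the correct physical limits", {
  sys <- ubl_pub_system(KD = 10)
  r <- seq(6.0, 7.2, length.out = 50)

  # omega -> 0: exponents vanish, a(r) constant and equal to the r0 sum
  a0 <- se_model(sys, r, rpm = 1e-6, cA0 = 50, cB0 = 40)
  flat <- sys$A$epsilon * 50 + sys$B$epsilon * 40 +
    sys$AB$epsilon * 50 * 40 / 10
  expect_equal(a0, rep(flat, 50), tolerance = 1e-9)

  # neutral buoyancy: vbar rho = 1 for every species
  rho <- 0.997
  sysn <- equilibrium_system(species("A", 9500, 1 / rho, 0.012),
                             species("B", 12500, 1 / rho, 0.015),
                             KD = 10, solvent_density = rho)
  an <- se_model(sysn, r, rpm = 30000, cA0 = 50, cB0 = 40)
  expect_equal(diff(range(an)), 0, tolerance = 1e-10)

  # KD -> Inf: the complex term vanishes
  a_noAB <- se_model(sys, r, rpm = 30000, cA0 = 50, cB0 = 40, KD = 1e12)
  two_species <- sys$A$epsilon * 50 *
    exp(aucsas:::.se_sigma(9500, 0.73, sys$solvent_density, 30000,
                           sys$temperature) *
          ((r * 1e-2)^2 - (6.0e-2)^2)) +
    sys$B$epsilon * 40 *
    exp(aucsas:::.se_sigma(12500, 0.73, sys$solvent_density, 30000,
                           sys$temperature) *
          ((r * 1e-2)^2 - (6.0e-2)^2))
  expect_equal(a_noAB, two_species, tolerance = 1e-6)
})

test_that("mass_action solves the equilibrium quadratic", {
  # tight binding: everything complexed (the approach is ~ sqrt(KD T))
  eq0 <- mass_action(1e-13, 100, 100)
  expect_equal(eq0$AB, 100, tolerance = 1e-6)
  # no binding
  eqI <- mass_action(1e12, 100, 100)
  expect_equal(eqI$AB, 0, tolerance = 1e-6)
  # the worked mid-affinity case
  eq <- mass_action(10, 100, 100)
  expect_equal(eq$AB, 72.984, tolerance = 1e-4)
  expect_equal(eq$free_A, 27.016, tolerance = 1e-4)
  expect_equal(eq$free_A * eq$free_B / eq$AB, 10, tolerance = 1e-9)
})

test_that("mass_action residuals stay below 1e-9 across a parameter sweep", {
  set.seed(11)
  for (i in 1:60) {
    KD <- 10^stats::runif(1, -2, 3)
    tA <- stats::runif(1, 0.1, 500)
    tB <- stats::runif(1, 0.1, 500)
    eq <- mass_action(KD, tA, tB)
    expect_true(all(c(eq$free_A, eq$free_B, eq$AB) >= 0))
    expect_lt(abs(eq$free_A + eq$AB - tA) / tA, 1e-12)
    expect_lt(abs(eq$free_B + eq$AB - tB) / tB, 1e-12)
    if (eq$AB > 0)
      expect_lt(abs(eq$free_A * eq$free_B / eq$AB - KD) / KD, 1e-9)
  }
})

test_that("a noiseless scan is fitted exactly", {
  sys <- ubl_pub_system(KD = 10)
  sc <- make_se_scans(sys, speeds = 30000,
                      loadings = list(c(A = 100, B = 100)),
                      noise = 0, seed = 1L,
                      radii = seq(6.0, 7.2, length.out = 120))
  fit <- global_fit_kd(sc, sys, sigma_a = 1e-6)
  expect_equal(fit$KD, 10, tolerance = 1e-6)
})

test_that("K_D is recovered from a noisy multi-speed design", {
  sys <- ubl_pub_system(KD = 10)
  scans <- make_se_scans(sys, speeds = c(20000, 30000, 35000),
                         loadings = list(c(A = 100, B = 100)),
                         noise = 0.005, seed = 23L,
                         radii = seq(6.0, 7.2, length.out = 120))
  fit <- global_fit_kd(scans, sys)
  expect_equal(fit$KD, 10, tolerance = 0.10)
  expect_true(is.finite(fit$KD_err) && fit$KD_err > 0)
  expect_equal(fit$chi2_reduced, 1, tolerance = 0.35)
})

test_that("forward model and global fit are a calibrated pair", {
  # 200 replicates: bias < 2%, 1-sigma coverage near the nominal 68%
  sys <- ubl_pub_system(KD = 10)
  res <- t(vapply(seq_len(200), function(r) {
    scans <- make_se_scans(sys, speeds = c(20000, 30000, 35000),
                           loadings = list(c(A = 100, B = 100)),
                           noise = 0.005, seed = 5000L + r,
                           radii = seq(6.0, 7.2, length.out = 120))
    fit <- global_fit_kd(scans, sys)
    c(KD = fit$KD, err = fit$KD_err)
  }, numeric(2)))
  expect_lt(abs(mean(res[, "KD"]) - 10) / 10, 0.02)
  cover <- mean(abs(res[, "KD"] - 10) <= res[, "err"])
  expect_gte(cover, 0.56)
  expect_lte(cover, 0.79)
})

test_that("wrong species constants inflate the fit chi-square", {
  sys <- ubl_pub_system(KD = 10)
  scans <- make_se_scans(sys, speeds = c(20000, 30000, 35000),
                         loadings = list(c(A = 100, B = 100)),
                         noise = 0.005, seed = 31L,
                         radii = seq(6.0, 7.2, length.out = 120))
  good <- global_fit_kd(scans, sys)
  sys_wrong <- equilibrium_system(species("A", 9500, 0.73, 0.012),
                                  species("B", 19000, 0.73, 0.015),
                                  KD = 10)
  bad <- global_fit_kd(scans, sys_wrong)
  expect_gt(bad$chi2_reduced, 5 * good$chi2_reduced)
})

test_that("decompose_complex recovers trivial and round-trip cases", {
  q <- exp(seq(log(0.03), log(0.7), length.out = 120))
  mk <- function(R) {
    I <- sphere_intensity(q, R)
    scattering_profile(q, I, pmax(0.01 * I, 1e-12))
  }
  iA <- mk(16); iB <- mk(18); iAB <- mk(22)

  # pure complex: c_A = c_B = 0 gives i_AB = i_exp
  mixp <- scattering_profile(q, iAB$intensity, iAB$sigma, concentration = 1)
  decp <- decompose_complex(mixp, iA, iB,
                            list(c_A = 0, c_B = 0, c_AB = 1, total = 1))
  expect_equal(decp$i_AB$intensity, iAB$intensity, tolerance = 1e-12)

  expect_error(decompose_complex(mixp, iA, iB,
                                 list(c_A = 0.5, c_B = 0.5, c_AB = 0)),
               "c_AB")

  # noiseless generator round trip is exact
  sys <- ubl_pub_system(KD = 10)
  mix <- make_equilibrium_saxs(sys, iA, iB, iAB, c(A = 100, B = 100),
                               noise = list(rel = 0, floor = 0), seed = 2L)
  dec <- decompose_complex(mix$i_exp, iA, iB,
                           mix$truth$concentrations$mass)
  expect_equal(dec$i_AB$intensity, iAB$intensity, tolerance = 1e-12)

  # noisy round trip: residuals consistent with the propagated sigma
  mixn <- make_equilibrium_saxs(sys, iA, iB, iAB, c(A = 100, B = 100),
                                noise = list(rel = 0.01, floor = 0),
                                seed = 3L)
  decn <- decompose_complex(mixn$i_exp, iA, iB,
                            mixn$truth$concentrations$mass)
  z <- (decn$i_AB$intensity - iAB$intensity) / decn$i_AB$sigma
  expect_lt(max(abs(z)), 4)
  expect_gt(mean(abs(z) < 2), 0.9)
})

test_that("decompose_complex is linear in the intensities", {
  q <- exp(seq(log(0.03), log(0.7), length.out = 60))
  mk <- function(R, k = 1) {
    I <- k * sphere_intensity(q, R)
    scattering_profile(q, I, pmax(0.01 * I, 1e-12))
  }
  conc <- list(c_A = 0.3, c_B = 0.4, c_AB = 0.8, total = 1.5)
  d1 <- decompose_complex(mk(20), mk(16), mk(18), conc)
  d2 <- decompose_complex(mk(20, 2), mk(16, 2), mk(18, 2), conc)
  expect_equal(d2$i_AB$intensity, 2 * d1$i_AB$intensity, tolerance = 1e-12)
})

test_that("the aggregation-free pre-check applies its thresholds", {
  ok <- component_table(1:2, c(0.6, 0.4))
  expect_true(check_aggregation_free(ok, expected_j = 1:2))

  with_5pct <- component_table(1:3, c(0.57, 0.38, 0.05))
  expect_false(check_aggregation_free(with_5pct, expected_j = 1:2))

  with_1pct <- component_table(1:3, c(0.59, 0.40, 0.01))
  expect_warning(pass <- check_aggregation_free(with_1pct, expected_j = 1:2),
                 "biased")
  expect_true(pass)
  expect_equal(attr(pass, "extra_fraction"), 0.01, tolerance = 1e-12)
})
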