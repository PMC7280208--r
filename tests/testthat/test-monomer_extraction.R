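test_that("forward fraction follows the weight-fraction arithmetic", {
  expect_equal(forward_fraction(component_table(1L, 1.0)), 1)
  expect_equal(forward_fraction(component_table(1:2, c(0.9, 0.1))),
               0.9 / (0.9 + 0.2), tolerance = 1e-12)
  expect_equal(forward_fraction(component_table(1:2, c(0.9, 0.1))),
               0.81818, tolerance = 1e-5)
  expect_error(forward_fraction(component_table(2:3, c(0.5, 0.5))),
               "monomer")
})

test_that("t1 depends only on fraction ratios (unit invariance)", {
  # same composition given as fractions and as mg/mL concentrations
  ct_frac <- component_table(1:3, c(0.90, 0.07, 0.03))
  ct_conc <- component_table(1:3, 2.29 * c(0.90, 0.07, 0.03),
                             values_are = "concentration")
  expect_equal(forward_fraction(ct_frac), forward_fraction(ct_conc),
               tolerance = 1e-14)
})

test_that("t1 equals the brute-force forward-intensity share of a mixture", {
  # independent oracle: forward intensities from the coordinate-sum S_j(0)
  ct <- bsa_fractions()
  w <- ct$weight_fraction; js <- ct$j
  fw <- vapply(seq_along(js), function(k)
    w[k] * oracle_structure_factor(1e-10, js[k], "close_packed", 70)[1] /
      js[k], numeric(1))
  expect_equal(forward_fraction(ct), fw[1] / sum(fw), tolerance = 1e-10)
})

test_that("monomer forward intensity splits the measured forward intensity", {
  ct <- component_table(1:2, c(0.9, 0.1))
  out <- monomer_forward_intensity(110, 1, ct)
  expect_equal(out$c1_i1_0, 90, tolerance = 1e-12)
  expect_equal(out$aggregate_forward, 20, tolerance = 1e-12)
  # monomer-only: i1(0) = i_exp(0)
  out1 <- monomer_forward_intensity(110, 2.29, component_table(1L, 1.0))
  expect_equal(out1$i1_0, 110 / 2.29, tolerance = 1e-12)
})

test_that("assign_high_q restricts to q > q* and validates the range", {
  p <- sphere_profile()
  h <- assign_high_q(p, 1 / 27.2)
  expect_true(all(h$q > 1 / 27.2))
  expect_equal(h$intensity, p$intensity[p$q > 1 / 27.2])
  expect_error(assign_high_q(p, 0.5), "above")
})

test_that("connect_low_q reproduces an exactly-Guinier input", {
  Rg <- 27.2
  q <- default_q(150, 0.01, 0.12)
  I <- exp(-(q * Rg)^2 / 3)
  p <- scattering_profile(q, I, 1e-6 * I)
  h <- assign_high_q(p, 1 / Rg)
  conn <- connect_low_q(1.0, h, 1 / Rg, q_low = q)
  expect_equal(conn$Rg1_star, Rg, tolerance = 1e-3)
  expect_lt(conn$mismatch, 1e-4)
  on_common <- conn$profile$q %in% q
  expect_equal(conn$profile$intensity[on_common],
               I[match(conn$profile$q[on_common], q)], tolerance = 1e-3)
  expect_length(conn$warnings, 0L)
})

test_that("connect_low_q stitches a sphere tail close to the true curve", {
  # the slope-matched plain-Guinier branch tracks the true sphere to ~1%
  # below q_c (the residual low-q bias is what the refinement step removes)
  p <- sphere_profile()   # Rg 27.2, I0 = 1
  h <- assign_high_q(p, 1 / 27.2)
  conn <- connect_low_q(1.0, h, 1 / 27.2, q_low = p$q)
  truth <- sphere_intensity(conn$profile$q, 27.2 * sqrt(5 / 3))
  expect_lt(max(abs(conn$profile$intensity / truth - 1)), 0.015)
  # above the connection point the stitch is the measured curve itself
  hi <- conn$profile$q >= conn$q_c
  expect_equal(conn$profile$intensity[hi],
               truth[hi], tolerance = 1e-9)
})

test_that("connect_low_q reports inconsistent forward intensity", {
  p <- sphere_profile()
  h <- assign_high_q(p, 1 / 27.2)
  conn <- connect_low_q(2.0, h, 1 / 27.2, q_low = p$q)  # I(0) inflated x2
  expect_gt(conn$mismatch, 0.10)
  expect_gt(length(conn$warnings), 0L)
})

test_that("refinement is stable on an already-consistent candidate", {
  # exactly-Guinier input: the candidate is already self-consistent, so the
  # refinement settles immediately and leaves Rg unchanged
  Rg <- 27.2
  q <- default_q(150, 0.01, 0.12)
  I <- exp(-(q * Rg)^2 / 3)
  p <- scattering_profile(q, I, 1e-6 * I)
  h <- assign_high_q(p, 1 / Rg)
  conn <- connect_low_q(1.0, h, 1 / Rg, q_low = q)
  res <- refine_monomer(conn$profile, 1.0, conn$q_c)
  expect_lte(res$iterations, 2L)
  expect_equal(res$Rg1, Rg, tolerance = 1e-6)

  # sphere input: refined Rg carries only the expansion-truncation bias
  ps <- sphere_profile()
  hs <- assign_high_q(ps, 1 / 27.2)
  cs <- connect_low_q(1.0, hs, 1 / 27.2, q_low = ps$q)
  rs <- refine_monomer(cs$profile, 1.0, cs$q_c)
  expect_equal(rs$Rg1, 27.2, tolerance = 0.01)
})

test_that("the pipeline is the identity for a monomer-only solution", {
  mx <- make_mixture(generator_spec(seed = 21L))
  res <- extract_monomer(mx$i_exp, component_table(1L, 1.0))
  expect_equal(res$t1, 1)
  expect_equal(res$Rg1, 27.2, tolerance = 0.01)
  # extracted per-mass curve tracks i_exp/c within a few noise sigmas
  iexp <- per_mass(mx$i_exp)
  common <- intersect(res$i1$q, iexp$q)
  d <- abs(res$i1$intensity[match(common, res$i1$q)] -
             iexp$intensity[match(common, iexp$q)])
  expect_lt(stats::median(d / iexp$sigma[match(common, iexp$q)]), 3)
})

test_that("a contaminated mixture is corrected: Rg shrinks toward truth", {
  ct <- bsa_fractions()
  mx <- make_mixture(generator_spec(fractions = ct, seed = 7L))
  res <- extract_monomer(mx$i_exp, ct)
  # aggregates inflate the apparent size; extraction removes the excess
  expect_gt(res$mixture_fit$Rg, 27.2)
  expect_lt(res$Rg1, res$mixture_fit$Rg)
  expect_equal(res$Rg1, 27.2, tolerance = 0.02)
  expect_equal(res$i1_0, 1.0, tolerance = 0.02)
  expect_true(res$q_star <= res$q_c)
})

test_that("forward-intensity conservation holds exactly", {
  ct <- bsa_fractions()
  mx <- make_mixture(generator_spec(fractions = ct, seed = 9L))
  res <- extract_monomer(mx$i_exp, ct)
  conc <- mx$i_exp$concentration
  # at q = 0: c1 i1(0) + aggregate share = c i_exp(0), by construction
  fwd <- monomer_forward_intensity(conc * res$mixture_fit$I0, conc, ct)
  expect_equal(fwd$c1_i1_0 + fwd$aggregate_forward,
               conc * res$mixture_fit$I0, tolerance = 1e-12)
  # on the measured grid: c1 i1(q) + c_a i_a(q) = c i_exp(q) exactly
  iexp <- per_mass(mx$i_exp)
  qa <- res$aggregate_intensity$q
  lhs <- res$c1 * res$i1$intensity[match(qa, res$i1$q)] +
    res$aggregate_intensity$intensity
  rhs <- conc * iexp$intensity[match(qa, iexp$q)]
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("the aggregate residual is positive at low angles", {
  ct <- component_table(1:2, c(0.94, 0.06))
  mx <- make_mixture(generator_spec(fractions = ct, seed = 5L))
  res <- extract_monomer(mx$i_exp, ct)
  low <- res$aggregate_intensity$q < res$q_star
  expect_true(all(res$aggregate_intensity$intensity[low] > 0))
})

test_that("aggregate-fraction policy warns above 12% and refuses above 25%", {
  ct20 <- component_table(1:2, c(0.80, 0.20))
  mx <- make_mixture(generator_spec(fractions = ct20, seed = 13L))
  expect_warning(res <- extract_monomer(mx$i_exp, ct20), "12%")
  expect_gt(length(res$warnings), 0L)

  ct30 <- component_table(1:2, c(0.70, 0.30))
  mx30 <- make_mixture(generator_spec(fractions = ct30, seed = 13L))
  expect_error(suppressWarnings(extract_monomer(mx30$i_exp, ct30)),
               "validity cap")
})

test_that("a visible low-q upturn is refused unless overridden", {
  # monomer curve plus a strong 1/q^2 aggregate tail
  q <- default_q()
  I <- 2.29 * sphere_intensity(q, 27.2 * sqrt(5 / 3))
  up <- 0.15 * I[1] * (q[1] / q)^2
  p <- scattering_profile(q, I + up, 0.002 * I, concentration = 2.29)
  ct <- bsa_fractions()
  expect_error(extract_monomer(p, ct), "upturn")
  expect_no_error(suppressWarnings(
    extract_monomer(p, ct, config = list(allow_upturn = TRUE))))
})
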