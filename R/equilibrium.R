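#' Define a sedimenting species
#'
#' @param name Species name.
#' @param M Molecular weight \[Da\].
#' @param vbar Partial specific volume \[mL/g\] (typically 0.70-0.75 for
#'   proteins).
#' @param epsilon Extinction coefficient including the optical path,
#'   \[AU per uM\] (i.e. molar extinction x path / 1e6).
#' @return An object of class `auc_species`.
#' @export
species <- function(name, M, vbar, epsilon) {
  stopifnot(is.finite(M), M > 0, is.finite(vbar), vbar > 0,
            is.finite(epsilon), epsilon >= 0)
  structure(list(name = name, M = M, vbar = vbar, epsilon = epsilon),
            class = "auc_species")
}

#' Define an A + B <-> AB equilibrium system
#'
#' The complex AB has M_AB = M_A + M_B, mass-weighted partial specific
#' volume, and (by default) additive extinction eps_AB = eps_A + eps_B.
#'
#' @param A,B [species()] objects.
#' @param KD Dissociation constant \[uM\] (may be `NA` before fitting).
#' @param loadings List of named vectors `c(A = , B = )` \[uM\]: the loading
#'   concentrations of the measured scans.
#' @param solvent_density Solvent density rho \[g/mL\].
#' @param temperature Absolute temperature \[K\].
#' @param epsilon_AB Optional complex extinction \[AU/uM\]; default additive.
#' @return An object of class `equilibrium_system`.
#' @export
equilibrium_system <- function(A, B, KD = NA_real_, loadings = list(),
                               solvent_density = 0.997,
                               temperature = 298.15,
                               epsilon_AB = NULL) {
  stopifnot(inherits(A, "auc_species"), inherits(B, "auc_species"))
  if (!is.na(KD) && KD <= 0) stop("KD must be positive [uM]")
  M_AB <- A$M + B$M
  AB <- species(paste0(A$name, "-", B$name), M_AB,
                (A$M * A$vbar + B$M * B$vbar) / M_AB,
                if (is.null(epsilon_AB)) A$epsilon + B$epsilon else epsilon_AB)
  structure(list(A = A, B = B, AB = AB, KD = KD, loadings = loadings,
                 solvent_density = solvent_density,
                 temperature = temperature),
            class = "equilibrium_system")
}

# reduced buoyant molar mass term sigma_X = omega^2 M (1 - vbar rho) / (2RT),
# in 1/m^2 (M in Da, rpm in r.p.m., T in K)
.se_sigma <- function(M, vbar, rho, rpm, temperature) {
  omega <- 2 * pi * rpm / 60
  R_gas <- 8.31446261815324          # J / (mol K)
  omega^2 * (M * 1e-3) * (1 - vbar * rho) / (2 * R_gas * temperature)
}

#' Sedimentation-equilibrium absorbance model
#'
#' Radial absorbance of the A + B <-> AB system at equilibrium in the
#' centrifugal field:
#' a(r) = eps_A cA0 exp\[sigma_A (r^2 - r0^2)\]
#'      + eps_B cB0 exp\[sigma_B (r^2 - r0^2)\]
#'      + eps_AB (cA0 cB0 / KD) exp\[sigma_AB (r^2 - r0^2)\] + baseline,
#' with sigma_X = omega^2 M_X (1 - vbar_X rho) / (2RT). The complex term is
#' the molar mass-action form of the reference-radius concentration; it is
#' algebraically identical to the mass-concentration form with the factor
#' M_AB/(M_A M_B KD).
#'
#' @param system An [equilibrium_system()].
#' @param radius Radii \[cm\].
#' @param rpm Rotor speed \[r.p.m.\].
#' @param cA0,cB0 Free-species molar concentrations at the reference radius
#'   \[uM\].
#' @param KD Dissociation constant \[uM\]; defaults to `system$KD`.
#' @param baseline Additive baseline offset \[AU\].
#' @param r0 Reference radius \[cm\]; default the innermost radius.
#' @param temperature Override of the system temperature \[K\].
#' @return Numeric vector of absorbances \[AU\].
#' @export
se_model <- function(system, radius, rpm, cA0, cB0, KD = system$KD,
                     baseline = 0, r0 = min(radius),
                     temperature = system$temperature) {
  stopifnot(inherits(system, "equilibrium_system"))
  if (cA0 < 0 || cB0 < 0) stop("reference concentrations must be >= 0")
  if (!is.finite(KD) || KD <= 0) stop("KD must be positive [uM]")
  rho <- system$solvent_density
  r2 <- (radius * 1e-2)^2 - (r0 * 1e-2)^2    # cm -> m
  sA <- .se_sigma(system$A$M, system$A$vbar, rho, rpm, temperature)
  sB <- .se_sigma(system$B$M, system$B$vbar, rho, rpm, temperature)
  sAB <- .se_sigma(system$AB$M, system$AB$vbar, rho, rpm, temperature)
  system$A$epsilon * cA0 * exp(sA * r2) +
    system$B$epsilon * cB0 * exp(sB * r2) +
    system$AB$epsilon * (cA0 * cB0 / KD) * exp(sAB * r2) +
    baseline
}

#' Global fit of the dissociation constant over multiple SE scans
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the sedimentation-equilibrium model to several scans
#' simultaneously: a single K_D is shared across all scans while the
#' reference-radius concentrations cA0, cB0 (and, optionally, an additive
#' baseline) are free per scan. K_D and the concentrations are fitted in log
#' space to enforce positivity; the quoted K_D error is the delta-method
#' 1-sigma from the covariance at the optimum.
#'
#' @param scans List of [se_scan()] objects (>= 1; >= 2 recommended).
#' @param system An [equilibrium_system()] with species constants.
#' @param fit_baseline Include a per-scan additive baseline (default TRUE).
#' @param KD_init Initial K_D \[uM\]; default: mean total loading.
#' @param sigma_a Assumed absorbance noise \[AU\] for chi-square scaling
#'   (default 0.005).
#' @param max_iter Iteration cap for the optimizer.
#' @return An object of class `kd_fit`: list with `KD`, `KD_err`, `c0`
#'   (per-scan data.frame of cA0, cB0, baseline), `chi2_per_scan`,
#'   `chi2_reduced`, `fitted` (list of predicted curves), `converged`,
#'   `info`.
#' @export
global_fit_kd <- function(scans, system, fit_baseline = TRUE,
                          KD_init = NULL, sigma_a = 0.005,
                          max_iter = 200L) {
  if (inherits(scans, "se_scan")) scans <- list(scans)
  stopifnot(length(scans) >= 1L, inherits(system, "equilibrium_system"))
  ns <- length(scans)
  if (is.null(KD_init))
    KD_init <- mean(vapply(scans, function(s) sum(s$loading), numeric(1)))
  # start concentrations: half the loading (the gradient depletes the meniscus)
  par0 <- c(log(KD_init),
            unlist(lapply(scans, function(s) {
      c(log(0.5 * max(s$loading[["A"]], 1e-3)),
        log(0.5 * max(s$loading[["B"]], 1e-3)),
        if (fit_baseline) 0)
    })))
  k <- if (fit_baseline) 3L else 2L
  resid_fn <- function(p) {
    KD <- exp(p[1L])
    unlist(lapply(seq_len(ns), function(i) {
      off <- 1L + (i - 1L) * k
      a_hat <- se_model(system, scans[[i]]$radius, scans[[i]]$rpm,
                        cA0 = exp(p[off + 1L]), cB0 = exp(p[off + 2L]),
                        KD = KD,
                        baseline = if (fit_baseline) p[off + 3L] else 0,
                        temperature = scans[[i]]$temperature)
      (a_hat - scans[[i]]$absorbance) / sigma_a
    }))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12,
                              ptol = 1e-12))
  if (fit$info %in% c(0L, 9L))
    stop("global K_D fit did not converge: ", fit$message)
  p <- fit$par
  KD <- exp(p[1L])
  # covariance at the optimum; fall back to the Hessian inverse scaled by
  # the residual variance when vcov fails on a near-perfect fit
  dof0 <- length(fit$fvec) - length(p)
  cv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(cv)) {
    # fresh finite-difference Jacobian at the optimum
    J <- pracma::jacobian(resid_fn, p)
    if (qr(J)$rank < length(p))
      stop("rank-deficient Jacobian: K_D is not identifiable from these scans")
    cv <- tryCatch(solve(crossprod(J)) * fit$deviance / max(dof0, 1L),
                   error = function(e) NULL)
    if (is.null(cv))
      stop("rank-deficient Jacobian: K_D is not identifiable from these scans")
  }
  KD_err <- KD * sqrt(max(cv[1L, 1L], 0))
  c0 <- do.call(rbind, lapply(seq_len(ns), function(i) {
    off <- 1L + (i - 1L) * k
    data.frame(scan = i, rpm = scans[[i]]$rpm,
               cA0 = exp(p[off + 1L]), cB0 = exp(p[off + 2L]),
               baseline = if (fit_baseline) p[off + 3L] else 0)
  }))
  res <- split(fit$fvec, rep(seq_len(ns),
                             vapply(scans, function(s) length(s$radius),
                                    integer(1))))
  chi2_scan <- vapply(res, function(r) sum(r^2) / length(r), numeric(1))
  dof <- length(fit$fvec) - length(p)
  fitted <- lapply(seq_len(ns), function(i) {
    se_model(system, scans[[i]]$radius, scans[[i]]$rpm,
             cA0 = c0$cA0[i], cB0 = c0$cB0[i], KD = KD,
             baseline = c0$baseline[i],
             temperature = scans[[i]]$temperature)
  })
  structure(list(KD = KD, KD_err = KD_err, c0 = c0,
                 chi2_per_scan = chi2_scan,
                 chi2_reduced = sum(fit$fvec^2) / max(dof, 1L),
                 fitted = fitted, converged = TRUE, info = fit$info,
                 sigma_a = sigma_a),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("<kd_fit>\n")
  cat(sprintf("  K_D = %.4g +/- %.2g uM\n", x$KD, x$KD_err))
  cat(sprintf("  chi2_reduced = %.3g over %d scan(s)\n",
              x$chi2_reduced, nrow(x$c0)))
  invisible(x)
}

#' Mass-action concentrations of an A + B <-> AB mixture
#'
#' Solves \[A\]\[B\]/\[AB\] = K_D under the conservation laws
#' \[A\] + \[AB\] = total_A and \[B\] + \[AB\] = total_B. The complex
#' concentration is the smaller root of the quadratic
#' AB^2 - (tA + tB + KD) AB + tA tB = 0, evaluated in the numerically
#' stable product form.
#'
#' @param KD Dissociation constant \[uM\].
#' @param total_A,total_B Total molar concentrations \[uM\].
#' @return List: `free_A`, `free_B`, `AB` \[uM\].
#' @export
mass_action <- function(KD, total_A, total_B) {
  stopifnot(is.finite(KD), KD > 0, total_A >= 0, total_B >= 0)
  S <- total_A + total_B + KD
  disc <- sqrt(S^2 - 4 * total_A * total_B)
  AB <- 2 * total_A * total_B / (S + disc)   # stable smaller root
  list(free_A = total_A - AB, free_B = total_B - AB, AB = AB)
}

#' Convert molar to mass concentration
#' @param c_uM Molar concentration \[uM\].
#' @param M Molecular weight \[Da\].
#' @return Mass concentration \[mg/mL\].
#' @export
molar_to_mass <- function(c_uM, M) c_uM * M * 1e-6

#' Equilibrium mass concentrations at a SAXS loading
#'
#' Applies [mass_action()] at the given loading and converts to the mass
#' concentrations entering the subtraction decomposition.
#'
#' @param system An [equilibrium_system()] with a fitted/known `KD`.
#' @param total_A,total_B Loading concentrations \[uM\].
#' @param KD Override of `system$KD` \[uM\].
#' @return List: `molar` (free_A, free_B, AB in uM), `mass`
#'   (c_A, c_B, c_AB, total in mg/mL).
#' @export
equilibrium_concentrations <- function(system, total_A, total_B,
                                       KD = system$KD) {
  stopifnot(inherits(system, "equilibrium_system"))
  eq <- mass_action(KD, total_A, total_B)
  mass <- list(c_A = molar_to_mass(eq$free_A, system$A$M),
               c_B = molar_to_mass(eq$free_B, system$B$M),
               c_AB = molar_to_mass(eq$AB, system$AB$M))
  mass$total <- mass$c_A + mass$c_B + mass$c_AB
  list(molar = eq, mass = mass)
}

#' Extract the complex scattering profile by subtraction
#'
#' i_AB(q) = \[c i_exp(q) - c_A i_A(q) - c_B i_B(q)\] / c_AB on the common
#' q grid (the measured mixture grid restricted to the overlap of all three
#' profiles; i_A and i_B are interpolated onto it). Uncertainties are
#' propagated in quadrature, including concentration uncertainties if given.
#'
#' @param i_exp Mixture profile, per-mass ([scattering_profile]); its
#'   `concentration` (or `conc$total`) supplies c.
#' @param i_A,i_B Per-mass component profiles.
#' @param conc List with `c_A`, `c_B`, `c_AB` \[mg/mL\] (e.g.
#'   `equilibrium_concentrations(...)$mass`), optionally `total` and
#'   1-sigma errors `c_A_err`, `c_B_err`, `c_AB_err`.
#' @return An object of class `complex_extraction_result`: list with `i_AB`
#'   ([scattering_profile]), `concentrations`, and the inputs' common grid
#'   summary.
#' @export
decompose_complex <- function(i_exp, i_A, i_B, conc) {
  stopifnot(inherits(i_exp, "scattering_profile"),
            inherits(i_A, "scattering_profile"),
            inherits(i_B, "scattering_profile"))
  if (is.null(conc$c_AB) || conc$c_AB <= 0)
    stop("c_AB must be positive to extract the complex profile")
  ctot <- if (!is.null(conc$total)) conc$total
          else if (!is.null(i_exp$concentration)) i_exp$concentration
          else conc$c_A + conc$c_B + conc$c_AB
  q_lo <- max(min(i_exp$q), min(i_A$q), min(i_B$q))
  q_hi <- min(max(i_exp$q), max(i_A$q), max(i_B$q))
  if (q_lo >= q_hi) stop("q grids of the three profiles do not overlap")
  keep <- i_exp$q >= q_lo & i_exp$q <= q_hi
  q <- i_exp$q[keep]
  iexp <- per_mass(i_exp)
  eA <- regrid(i_A, q); eB <- regrid(i_B, q)
  num <- ctot * iexp$intensity[keep] -
    conc$c_A * eA$intensity - conc$c_B * eB$intensity
  iAB <- num / conc$c_AB
  var <- (ctot * iexp$sigma[keep])^2 +
    (conc$c_A * eA$sigma)^2 + (conc$c_B * eB$sigma)^2
  if (!is.null(conc$c_A_err)) var <- var + (conc$c_A_err * eA$intensity)^2
  if (!is.null(conc$c_B_err)) var <- var + (conc$c_B_err * eB$intensity)^2
  sAB <- sqrt(var) / conc$c_AB
  if (!is.null(conc$c_AB_err))
    sAB <- sqrt(sAB^2 + (conc$c_AB_err / conc$c_AB * iAB)^2)
  structure(list(
    i_AB = scattering_profile(q, iAB, sAB,
                              label = paste0(i_exp$label, " [complex]")),
    concentrations = conc, total_concentration = ctot,
    q_range = c(q_lo, q_hi)),
    class = "complex_extraction_result")
}

#' @export
print.complex_extraction_result <- function(x, ...) {
  cat("<complex_extraction_result>\n")
  cat(sprintf("  c_A = %.4g, c_B = %.4g, c_AB = %.4g mg/mL\n",
              x$concentrations$c_A, x$concentrations$c_B,
              x$concentrations$c_AB))
  cat(sprintf("  i_AB on %d points, q in [%.4g, %.4g] 1/A\n",
              length(x$i_AB$q), x$q_range[1L], x$q_range[2L]))
  invisible(x)
}

#' Check that a mixture is aggregation-free
#'
#' Before SE-AUC, sedimentation velocity of the mixture must show only the
#' species of the equilibrium (A, B, AB). Any extra species carrying more
#' than `fail_threshold` of the mass fails the check; extra mass above
#' `warn_threshold` passes with a warning.
#'
#' @param components A [component_table] of the mixture's c(s) peaks; rows
#'   are matched to the equilibrium species via `expected_j` (aggregation
#'   numbers / row identifiers regarded as A, B, AB).
#' @param expected_j Integer vector of `j` values that belong to the
#'   equilibrium (default 1:2 plus any j given `mass` matching within 5%).
#' @param fail_threshold Maximum tolerated extra weight fraction (default
#'   0.02).
#' @param warn_threshold Warn above this extra fraction (default 0.005).
#' @return Logical: `TRUE` (pass) or `FALSE` (fail), with attribute
#'   `extra_fraction`.
#' @export
check_aggregation_free <- function(components, expected_j = c(1L, 2L),
                                   fail_threshold = 0.02,
                                   warn_threshold = 0.005) {
  stopifnot(inherits(components, "component_table"))
  extra <- sum(components$weight_fraction[!components$j %in% expected_j])
  pass <- extra <= fail_threshold
  if (pass && extra > warn_threshold)
    warning(sprintf(
      "unassigned species carry %.1f%% of the mass; SE-AUC results may be biased",
      100 * extra))
  structure(pass, extra_fraction = extra)
}
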