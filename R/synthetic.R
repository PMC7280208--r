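#' Analytic sphere form factor
#'
#' Normalized scattering intensity of a homogeneous sphere of radius R:
#' I(q) = \[3 (sin x - x cos x) / x^3\]^2 with x = qR, I(0) = 1.
#' The exact radius of gyration is sqrt(3/5) R.
#'
#' @param q Scattering vector magnitudes \[1/Angstrom\].
#' @param R Sphere radius \[Angstrom\].
#' @return Numeric intensity vector, I(0) = 1.
#' @export
sphere_intensity <- function(q, R) {
  stopifnot(R > 0)
  x <- q * R
  f <- numeric(length(x))
  small <- abs(x) < 1e-3
  f[small] <- 1 - x[small]^2 / 10 + x[small]^4 / 280
  xs <- x[!small]
  f[!small] <- 3 * (sin(xs) - xs * cos(xs)) / xs^3
  f^2
}

#' Debye random-coil (Gaussian chain) intensity
#'
#' I(q) = 2 (exp(-x) + x - 1) / x^2 with x = (q Rg)^2; I(0) = 1.
#'
#' @param q Scattering vector magnitudes \[1/Angstrom\].
#' @param Rg Chain radius of gyration \[Angstrom\].
#' @return Numeric intensity vector.
#' @export
debye_chain_intensity <- function(q, Rg) {
  stopifnot(Rg > 0)
  x <- (q * Rg)^2
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 12
  xs <- x[!small]
  out[!small] <- 2 * (exp(-xs) + xs - 1) / xs^2
  out
}

#' Orientation-averaged ellipsoid-of-revolution intensity
#'
#' Homogeneous ellipsoid with polar semi-axis `a` and equatorial semi-axis
#' `b`; the orientation average is computed by Gauss-Legendre quadrature
#' over the axis angle. I(0) = 1; exact Rg = sqrt((a^2 + 2 b^2)/5).
#'
#' @param q Scattering vector magnitudes \[1/Angstrom\].
#' @param a,b Semi-axes \[Angstrom\].
#' @param n_nodes Quadrature nodes (default 64).
#' @return Numeric intensity vector.
#' @export
ellipsoid_intensity <- function(q, a, b, n_nodes = 64L) {
  stopifnot(a > 0, b > 0)
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  # effective radius at axis-cosine u: r(u) = sqrt(a^2 u^2 + b^2 (1 - u^2))
  reff <- sqrt(a^2 * gl$x^2 + b^2 * (1 - gl$x^2))
  vapply(q, function(qi) sum(gl$w * sphere_intensity(qi * reff, 1)),
         numeric(1))
}

# exact Rg of the supported analytic shapes
.shape_rg <- function(shape) {
  switch(shape$type,
         sphere = sqrt(3 / 5) * shape$R,
         debye_chain = shape$Rg,
         ellipsoid = sqrt((shape$a^2 + 2 * shape$b^2) / 5),
         stop("unknown shape type: ", shape$type))
}

.shape_intensity <- function(q, shape) {
  switch(shape$type,
         sphere = sphere_intensity(q, shape$R),
         debye_chain = debye_chain_intensity(q, shape$Rg),
         ellipsoid = ellipsoid_intensity(q, shape$a, shape$b),
         stop("unknown shape type: ", shape$type))
}

#' Specification for the synthetic-mixture generator
#'
#' Defaults emulate the demonstration conditions of the method: a globular
#' monomer with Rg = 27.2 Angstrom (sphere radius 27.2 sqrt(5/3)), total
#' mass concentration 2.29 mg/mL, a q grid of 150 log-spaced points on
#' 0.010-0.20 1/Angstrom, and 1% relative Gaussian noise.
#'
#' @param shape List: `type` ("sphere", "debye_chain" or "ellipsoid") plus
#'   its parameters (`R`; `Rg`; `a`, `b`).
#' @param fractions A [component_table].
#' @param concentration Total mass concentration \[mg/mL\].
#' @param noise List: `rel` (sigma/I) and `floor` (absolute sigma).
#' @param qgrid List: `qmin`, `qmax` \[1/Angstrom\], `n`, `spacing`
#'   ("log" or "linear").
#' @param geometry Oligomer geometry for the aggregates.
#' @param d Contact distance override \[Angstrom\]; default sphere-equivalent.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(shape = list(type = "sphere",
                                        R = 27.2 * sqrt(5 / 3)),
                           fractions = component_table(1L, 1.0),
                           concentration = 2.29,
                           noise = list(rel = 0.01, floor = 0),
                           qgrid = list(qmin = 0.010, qmax = 0.20,
                                        n = 150L, spacing = "log"),
                           geometry = "close_packed", d = NULL,
                           seed = 1L) {
  stopifnot(inherits(fractions, "component_table"))
  noise <- utils::modifyList(list(rel = 0.01, floor = 0), noise)
  qgrid <- utils::modifyList(list(qmin = 0.010, qmax = 0.20, n = 150L,
                                  spacing = "log"), qgrid)
  structure(list(shape = shape, fractions = fractions,
                 concentration = concentration, noise = noise,
                 qgrid = qgrid, geometry = geometry, d = d,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

.make_qgrid <- function(qgrid) {
  if (identical(qgrid$spacing, "log"))
    exp(seq(log(qgrid$qmin), log(qgrid$qmax), length.out = qgrid$n))
  else
    seq(qgrid$qmin, qgrid$qmax, length.out = qgrid$n)
}

#' Generate a synthetic aggregate-contaminated measurement
#'
#' Forward model of the multi-component intensity: builds the analytic
#' monomer per-mass profile i1 (normalized to i1(0) = 1), the oligomer
#' per-mass intensities i_j from the Debye geometry model, and sums
#' I(q) = c sum_j w_j i_j(q), then adds heteroscedastic Gaussian noise
#' sigma(q) = rel * I(q) + floor. The returned truth bundle carries the
#' noise-free monomer profile and the exact Rg1, t1 and i1(0).
#'
#' @param spec A [generator_spec()].
#' @return List: `i_exp` (absolute-scale [scattering_profile] with the
#'   concentration attached), `truth` (list: `i1`, `Rg1`, `t1`, `i1_0`,
#'   `i_mix_0`, `fractions`, `seed`).
#' @export
make_mixture <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  q <- .make_qgrid(spec$qgrid)
  Rg1 <- .shape_rg(spec$shape)
  i1_int <- .shape_intensity(q, spec$shape)
  i1 <- scattering_profile(q, i1_int, pmax(1e-12, 1e-6 * i1_int),
                           label = sprintf("synthetic %s monomer",
                                           spec$shape$type))
  model <- oligomer_model(geometry = spec$geometry,
                          j_max = max(4L, max(spec$fractions$j)),
                          d = spec$d)
  # direct forward summation of the per-mass mixture intensity
  w <- spec$fractions$weight_fraction
  js <- spec$fractions$j
  i_mix <- Reduce(`+`, lapply(seq_along(js), function(k) {
    w[k] * oligomer_intensity(i1, js[k], model, Rg1 = Rg1)$intensity
  }))
  I_abs <- spec$concentration * i_mix
  sig <- spec$noise$rel * I_abs + spec$noise$floor
  set.seed(spec$seed)
  I_obs <- I_abs + stats::rnorm(length(q), 0, sig)
  sig_rep <- pmax(sig, 1e-12)
  list(
    i_exp = scattering_profile(q, I_obs, sig_rep,
                               concentration = spec$concentration,
                               label = "synthetic mixture"),
    truth = list(i1 = i1, Rg1 = Rg1,
                 t1 = forward_fraction(spec$fractions),
                 i1_0 = 1.0, i_mix_0 = sum(w * js),
                 fractions = spec$fractions, seed = spec$seed))
}

#' Generate a synthetic equilibrium-mixture SAXS measurement
#'
#' Computes the mass-action concentrations at the loading, sums
#' c i_exp = c_A i_A + c_B i_B + c_AB i_AB, and adds Gaussian noise.
#'
#' @param system An [equilibrium_system()] with `KD` set \[uM\].
#' @param i_A,i_B,i_AB Per-mass component profiles on a common grid
#'   (interpolated onto `i_A`'s grid if needed).
#' @param loading Named vector `c(A = , B = )` \[uM\].
#' @param noise List: `rel`, `floor` (as in [generator_spec()]).
#' @param seed Integer seed.
#' @return List: `i_exp` (absolute scale, concentration attached), `truth`
#'   (list: `i_AB`, `concentrations`, `seed`).
#' @export
make_equilibrium_saxs <- function(system, i_A, i_B, i_AB, loading,
                                  noise = list(rel = 0.01, floor = 0),
                                  seed = 1L) {
  stopifnot(inherits(system, "equilibrium_system"))
  noise <- utils::modifyList(list(rel = 0.01, floor = 0), noise)
  cc <- equilibrium_concentrations(system, loading[["A"]], loading[["B"]])
  q <- i_A$q
  eB <- regrid(i_B, pmax(pmin(q, max(i_B$q)), min(i_B$q)))
  eAB <- regrid(i_AB, pmax(pmin(q, max(i_AB$q)), min(i_AB$q)))
  I_abs <- cc$mass$c_A * i_A$intensity + cc$mass$c_B * eB$intensity +
    cc$mass$c_AB * eAB$intensity
  sig <- noise$rel * I_abs + noise$floor
  set.seed(as.integer(seed))
  I_obs <- I_abs + stats::rnorm(length(q), 0, sig)
  list(
    i_exp = scattering_profile(q, I_obs, pmax(sig, 1e-12),
                               concentration = cc$mass$total,
                               label = "synthetic equilibrium mixture"),
    truth = list(i_AB = i_AB, concentrations = cc, seed = as.integer(seed)))
}

# reference-radius concentrations consistent with mass conservation in a
# sector-shaped cell (integral weighted by r), by fixed-point iteration
.se_reference_conc <- function(system, radius, rpm, loading, KD,
                               temperature) {
  rho <- system$solvent_density
  r2 <- (radius * 1e-2)^2 - (min(radius) * 1e-2)^2
  wgt <- radius / sum(radius)
  eA <- exp(.se_sigma(system$A$M, system$A$vbar, rho, rpm, temperature) * r2)
  eB <- exp(.se_sigma(system$B$M, system$B$vbar, rho, rpm, temperature) * r2)
  eAB <- exp(.se_sigma(system$AB$M, system$AB$vbar, rho, rpm,
                       temperature) * r2)
  cA0 <- 0.5 * loading[["A"]]; cB0 <- 0.5 * loading[["B"]]
  for (it in seq_len(200L)) {
    tA <- cA0 * sum(wgt * eA) + (cA0 * cB0 / KD) * sum(wgt * eAB)
    tB <- cB0 * sum(wgt * eB) + (cA0 * cB0 / KD) * sum(wgt * eAB)
    fA <- loading[["A"]] / tA; fB <- loading[["B"]] / tB
    cA0 <- cA0 * fA; cB0 <- cB0 * fB
    if (max(abs(c(fA, fB) - 1)) < 1e-12) break
  }
  c(cA0 = cA0, cB0 = cB0)
}

#' Generate synthetic sedimentation-equilibrium scans
#'
#' Evaluates the equilibrium absorbance model on a radial grid for every
#' speed x loading combination, with reference-radius concentrations chosen
#' so that the radially averaged totals match the loading (mass conservation
#' in a sector cell), plus Gaussian absorbance noise.
#'
#' @param system An [equilibrium_system()] with `KD` set \[uM\].
#' @param speeds Rotor speeds \[r.p.m.\].
#' @param loadings List of named vectors `c(A = , B = )` \[uM\].
#' @param noise Absorbance noise sigma \[AU\] (default 0.005).
#' @param seed Integer seed.
#' @param radii Radial grid \[cm\] (default 200 points on 6.0-7.2).
#' @return List of [se_scan()] objects (one per speed x loading), with the
#'   generating `cA0`, `cB0` attached as attribute `truth`.
#' @export
make_se_scans <- function(system, speeds = c(20000, 30000, 35000),
                          loadings = list(c(A = 100, B = 100),
                                          c(A = 75, B = 75),
                                          c(A = 50, B = 50)),
                          noise = 0.005, seed = 1L,
                          radii = seq(6.0, 7.2, length.out = 200L)) {
  stopifnot(inherits(system, "equilibrium_system"), is.finite(system$KD))
  set.seed(as.integer(seed))
  out <- list()
  for (ld in loadings) for (rpm in speeds) {
    c0 <- .se_reference_conc(system, radii, rpm, ld, system$KD,
                             system$temperature)
    a <- se_model(system, radii, rpm, cA0 = c0[["cA0"]], cB0 = c0[["cB0"]],
                  KD = system$KD)
    a_obs <- a + stats::rnorm(length(radii), 0, noise)
    sc <- se_scan(radii, a_obs, rpm = rpm, loading = ld,
                  temperature = system$temperature)
    attr(sc, "truth") <- list(cA0 = c0[["cA0"]], cB0 = c0[["cB0"]],
                              KD = system$KD)
    out[[length(out) + 1L]] <- sc
  }
  out
}
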