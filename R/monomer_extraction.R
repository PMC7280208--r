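#' Forward-intensity fraction of the monomer
#'
#' The share t1 of the total forward scattering contributed by the monomer.
#' Because per-mass forward intensity is proportional to the scatterer mass,
#' t1 = c1 i1(0) / (c i(0)) = w1 / sum_j w_j j, which depends only on the
#' AUC-measured weight-fraction ratios.
#'
#' @param components A [component_table] with exactly one monomer row (j = 1).
#' @return t1 in (0, 1\].
#' @export
forward_fraction <- function(components) {
  stopifnot(inherits(components, "component_table"))
  w1 <- components$weight_fraction[components$j == 1L]
  if (length(w1) != 1L)
    stop("component table must contain exactly one monomer entry (j = 1)")
  w1 / sum(components$weight_fraction * components$j)
}

#' Monomer forward intensity from the mixture's
#'
#' Splits the Guinier-extrapolated total forward intensity c i_exp(0) into
#' the monomer part c1 i1(0) = t1 c i_exp(0) and the aggregate excess
#' (1 - t1) c i_exp(0), and returns the per-mass monomer forward intensity
#' i1(0) = t1 c i_exp(0) / c1.
#'
#' @param ci_exp_0 Total forward intensity c i_exp(0) (absolute scale).
#' @param conc Total mass concentration c \[mg/mL\].
#' @param components A [component_table].
#' @return List: `i1_0` (per-mass), `c1_i1_0`, `aggregate_forward`, `t1`,
#'   `c1`.
#' @export
monomer_forward_intensity <- function(ci_exp_0, conc, components) {
  stopifnot(is.finite(ci_exp_0), ci_exp_0 > 0, is.finite(conc), conc > 0)
  t1 <- forward_fraction(components)
  w1 <- components$weight_fraction[components$j == 1L]
  c1 <- w1 * conc
  if (c1 <= 0) stop("monomer concentration c1 is zero")
  list(i1_0 = t1 * ci_exp_0 / c1,
       c1_i1_0 = t1 * ci_exp_0,
       aggregate_forward = (1 - t1) * ci_exp_0,
       t1 = t1, c1 = c1)
}

#' Tentative high-angle monomer intensity
#'
#' Restriction of the measured per-mass intensity to q > q*: because the
#' aggregates are homo-oligomers of the monomer, the mixture and monomer
#' per-mass intensities agree above q* = 1/Rg1 up to the Debye-model bound
#' (attached as attribute `model_bound` when supplied).
#'
#' @param i_exp Per-mass measured profile ([scattering_profile]).
#' @param q_star Threshold \[1/Angstrom\], inside the grid.
#' @param model_bound Optional output of [max_deviation()] to attach.
#' @return A [scattering_profile] on q > q_star.
#' @export
assign_high_q <- function(i_exp, q_star, model_bound = NULL) {
  stopifnot(inherits(i_exp, "scattering_profile"))
  keep <- i_exp$q > q_star
  if (sum(keep) < 2L)
    stop("no grid points above q_star = ", q_star)
  out <- scattering_profile(i_exp$q[keep], i_exp$intensity[keep],
                            i_exp$sigma[keep],
                            label = paste0(i_exp$label, " [high-q]"))
  attr(out, "model_bound") <- model_bound
  out
}

# local logarithmic slope d ln I / d q^2 by weighted lm over a point window
.local_slope <- function(qw, Iw, sw) {
  fm <- stats::lm(log(Iw) ~ I(qw^2), weights = (Iw / sw)^2)
  s <- stats::coef(fm)[[2L]]
  se <- summary(fm)$coefficients[2L, "Std. Error"]
  c(slope = s, se = se)
}

#' Connect a Guinier branch to the high-angle intensity
#'
#' Builds the low-angle branch i1l(q) = i1(0) exp\[-(Rg1* q)^2/3\] and joins
#' it to the tentative high-angle branch at a connection point q_c where the
#' logarithmic slopes match: d ln i1l/dq^2 = d ln i1h/dq^2. Candidate q_c
#' values on the grid in \[q_star, 1.3/Rg1*\] are scanned; at each, the local
#' slope of ln i1h versus q^2 is estimated by a weighted linear fit over a
#' sliding window (max(7 points, 5% of the grid)), giving Rg1* =
#' sqrt(-3 slope); the candidate minimizing the log-intensity mismatch
#' between the two branches at q_c is selected.
#'
#' @param i1_0 Per-mass monomer forward intensity (the anchor).
#' @param i1h_star High-angle branch from [assign_high_q()].
#' @param q_star Lower bound of the scan.
#' @param q_low Optional q values below the connection point on which to
#'   evaluate the Guinier branch (e.g. the measured grid); default: the
#'   high-angle grid spacing continued down to q_star/4.
#' @param i1_0_err,Rg_err_scale Optional 1-sigma error on `i1_0` and an
#'   inflation factor for the slope error, used to propagate sigma onto the
#'   constructed branch.
#' @return List: `Rg1_star`, `q_c`, `profile` (stitched, on
#'   `c(q_low < q_c, q_h >= q_c)`), `mismatch` (relative branch mismatch at
#'   q_c), `slope_se`, `warnings` (character).
#' @export
connect_low_q <- function(i1_0, i1h_star, q_star, q_low = NULL,
                          i1_0_err = 0, Rg_err_scale = 1) {
  stopifnot(inherits(i1h_star, "scattering_profile"), i1_0 > 0)
  qh <- i1h_star$q; Ih <- i1h_star$intensity; sh <- i1h_star$sigma
  n <- length(qh)
  w <- max(7L, ceiling(0.05 * n))
  if (n < w + 2L)
    stop("high-angle branch too short to scan for a connection point")
  half <- w %/% 2L
  cand <- which(qh >= q_star)
  cand <- cand[cand > half & cand <= n - half]
  if (length(cand) == 0L) cand <- half + 1L
  best <- NULL
  for (ic in cand) {
    iw <- (ic - half):(ic + half)
    if (any(Ih[iw] <= 0)) next
    sl <- .local_slope(qh[iw], Ih[iw], sh[iw])
    if (!is.finite(sl[["slope"]]) || sl[["slope"]] >= 0) next
    Rg_c <- sqrt(-3 * sl[["slope"]])
    if (qh[ic] > 1.3 / Rg_c) next  # beyond the Guinier validity edge
    mis <- abs(log(i1_0) - (Rg_c * qh[ic])^2 / 3 - log(Ih[ic]))
    if (is.null(best) || mis < best$mis)
      best <- list(ic = ic, Rg = Rg_c, mis = mis, se = sl[["se"]])
  }
  if (is.null(best))
    stop("no physical Rg: ln-slope non-negative over the entire scan range")
  q_c <- qh[best$ic]
  warnings <- character(0)
  if (best$mis > log(1.10))
    warnings <- c(warnings, sprintf(
      "branch mismatch at q_c is %.1f%%: forward intensity and high-angle tail may be inconsistent",
      100 * (exp(best$mis) - 1)))
  if (is.null(q_low)) {
    dq <- stats::median(diff(qh))
    q_low <- seq(max(q_star / 4, dq), q_c - dq / 2, by = dq)
  } else {
    q_low <- q_low[q_low < q_c]
  }
  Rg_se <- 3 * best$se / (2 * best$Rg) * Rg_err_scale
  stitched <- .stitch_guinier(i1_0, best$Rg, q_c, q_low, i1h_star,
                              i1_0_err, Rg_se)
  list(Rg1_star = best$Rg, q_c = q_c, profile = stitched,
       mismatch = exp(best$mis) - 1, slope_se = best$se,
       warnings = warnings)
}

# compose the Guinier branch below q_c with the measured branch at/above q_c
.stitch_guinier <- function(i1_0, Rg, q_c, q_low, i1h, i1_0_err, Rg_err) {
  Il <- i1_0 * exp(-(Rg * q_low)^2 / 3)
  # first-order propagation through the Guinier formula
  rel2 <- (if (i1_0_err > 0) (i1_0_err / i1_0)^2 else 0) +
    (2 * Rg * q_low^2 / 3 * Rg_err)^2
  if (all(rel2 == 0) || i1_0_err <= 0) {
    rel_floor <- stats::median(i1h$sigma / pmax(i1h$intensity, .Machine$double.eps))
    rel2 <- rel2 + rel_floor^2
  }
  sl <- Il * sqrt(rel2)
  keep_h <- i1h$q >= q_c
  scattering_profile(c(q_low, i1h$q[keep_h]),
                     c(Il, i1h$intensity[keep_h]),
                     c(sl, i1h$sigma[keep_h]),
                     label = paste0(i1h$label, " [stitched]"))
}

#' Refine a stitched monomer profile
#'
#' Refines the stitched candidate with the extended (polynomial) Guinier
#' model, which tracks the form factor to a wider window than the plain
#' Guinier law. The model ln i1 = ln i1(0) + b q^2 + c q^4 (+ higher even
#' terms) is fitted, with the forward intensity held at the AUC-derived
#' anchor `i1_0`, to the candidate's measured portion (q >= `q_c`) inside
#' the window q Rg1 <= `qRg_max_ext`; only measured points inform the fit,
#' since the low-angle branch below `q_c` is itself a construction. The
#' window limit and Rg1 are iterated to self-consistency (tolerance `tol`
#' on the relative Rg1 change, cap `max_iter`; non-convergence is an error
#' carrying the last iterate in its `data` field). The refined low-angle
#' branch (q < `q_c`) is the fitted extended-Guinier curve, replacing the
#' semi-empirical plain-Guinier construction of the initial candidate.
#'
#' @param i1_star Stitched candidate ([scattering_profile]).
#' @param i1_0 Anchored per-mass forward intensity.
#' @param q_c Connection point from [connect_low_q()].
#' @param qRg_max_ext Extended-Guinier window limit (default 2.0).
#' @param order Extended-Guinier polynomial order (default 2).
#' @param tol Relative Rg1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List: `profile`, `Rg1`, `Rg1_err`, `fit` (final `guinier_result`),
#'   `iterations`.
#' @export
refine_monomer <- function(i1_star, i1_0, q_c, qRg_max_ext = 2.0,
                           order = 2L, tol = 1e-4, max_iter = 50L) {
  stopifnot(inherits(i1_star, "scattering_profile"), i1_0 > 0)
  meas <- i1_star$q >= q_c
  q <- i1_star$q[meas]; I <- i1_star$intensity[meas]
  s <- i1_star$sigma[meas]
  usable <- which(is.finite(I) & I > 0)
  need <- order + 2L
  if (length(usable) < need)
    stop("too few measured points above q_c to refine")
  win <- usable
  Rg <- NA_real_
  fit <- NULL
  converged <- FALSE
  seen <- list()
  for (it in seq_len(max_iter)) {
    fit <- .ext_guinier_lm(q[win], I[win], s[win], order, i1_0)
    new_win <- usable[q[usable] <= qRg_max_ext / fit$Rg]
    if (length(new_win) < need)
      new_win <- usable[seq_len(min(length(usable), need))]
    dRg <- if (is.finite(Rg)) abs(fit$Rg - Rg) / Rg else Inf
    cycled <- any(vapply(seen, identical, logical(1), y = new_win))
    Rg <- fit$Rg
    # the fit is deterministic given the window, so a stable window is a
    # fixed point; a revisited window means boundary chatter of an edge
    # point -- resolve it by refitting on the smaller of the two windows
    if (identical(new_win, win)) {
      converged <- TRUE
      break
    }
    if (cycled) {
      win <- if (length(new_win) < length(win)) new_win else win
      fit <- .ext_guinier_lm(q[win], I[win], s[win], order, i1_0)
      Rg <- fit$Rg
      converged <- TRUE
      break
    }
    seen[[length(seen) + 1L]] <- win
    win <- new_win
  }
  if (!converged) {
    cond <- structure(
      class = c("aucsas_convergence_error", "error", "condition"),
      list(message = sprintf(
        "refinement did not converge in %d iterations (last |dRg|/Rg = %.3g)",
        max_iter, dRg),
        call = NULL,
        data = list(Rg1 = Rg, iterations = it)))
    stop(cond)
  }
  # refined low-angle branch: the fitted extended-Guinier curve
  low_q <- i1_star$q[!meas]
  u <- outer(low_q^2, seq_along(fit$poly_coef), `^`)
  Il <- i1_0 * exp(drop(u %*% fit$poly_coef))
  rel_floor <- stats::median(s[usable] / I[usable])
  rel2 <- (2 * Rg * low_q^2 / 3 * fit$Rg_err)^2 + rel_floor^2
  prof <- scattering_profile(c(low_q, q), c(Il, I),
                             c(Il * sqrt(rel2), s),
                             label = i1_star$label)
  res_fit <- .guinier_result(fit, i1_star$q, which(meas)[win], prof)
  list(profile = prof, Rg1 = Rg, Rg1_err = fit$Rg_err,
       fit = res_fit, iterations = it)
}

#' Extract the monomer scattering profile from an aggregate-contaminated
#' measurement
#'
#' Full pipeline: (1) Guinier analysis of the measured curve (with upturn
#' diagnostics); (2) forward-intensity split via the AUC weight fractions
#' (t1); (3) per-mass monomer forward intensity i1(0); (4) tentative
#' high-angle assignment above q* = 1/Rg with the Debye-model deviation
#' bound; (5) slope-matched Guinier connection and extended-Guinier
#' refinement anchored at i1(0). Two outer passes are run so that q* is
#' finally based on the refined monomer Rg1 rather than the apparent
#' (aggregate-inflated) Rg of the mixture. Also returns the aggregate
#' residual curve c_a i_a(q) = c i_exp(q) - c1 i1(q).
#'
#' @param i_exp Measured profile ([scattering_profile]); if a concentration
#'   is stored the intensity is converted to per-mass internally, otherwise
#'   it is taken as already per-mass (c = 1).
#' @param components A [component_table] from SV-AUC.
#' @param config Optional list overriding defaults: `qRg_max` (1.3),
#'   `qRg_max_ext` (2.0), `order` (2), `geometry` ("close_packed"),
#'   `d` (NULL: sphere-equivalent from Rg1), `agg_warn` (0.12),
#'   `agg_refuse` (0.25), `allow_upturn` (FALSE), `tol` (1e-4),
#'   `max_iter` (50).
#' @return An object of class `monomer_extraction_result`: list with `i1`
#'   (per-mass monomer profile), `i1_0`, `Rg1`, `Rg1_err`, `t1`, `q_star`,
#'   `q_c`, `aggregate_intensity` (absolute-scale [scattering_profile]),
#'   `model_bound`, `mixture_fit` (Guinier of the input), `quality`,
#'   `iterations`, `warnings`.
#' @export
extract_monomer <- function(i_exp, components, config = list()) {
  stopifnot(inherits(i_exp, "scattering_profile"),
            inherits(components, "component_table"))
  cfg <- utils::modifyList(
    list(qRg_max = 1.3, qRg_max_ext = 2.0, order = 2L,
         geometry = "close_packed", d = NULL,
         agg_warn = 0.12, agg_refuse = 0.25, allow_upturn = FALSE,
         tol = 1e-4, max_iter = 50L),
    config)
  warnings <- character(0)

  conc <- if (is.null(i_exp$concentration)) 1 else i_exp$concentration
  iexp <- per_mass(i_exp)

  # aggregate-fraction validity policy
  fa <- aggregate_fraction(components)
  if (fa > cfg$agg_refuse)
    stop(sprintf(
      "aggregate fraction %.1f%% exceeds the %.0f%% validity cap of the method",
      100 * fa, 100 * cfg$agg_refuse))
  if (fa > cfg$agg_warn) {
    msg <- sprintf(
      "aggregate fraction %.1f%% exceeds %.0f%%: accuracy degrades beyond this boundary",
      100 * fa, 100 * cfg$agg_warn)
    warning(msg)
    warnings <- c(warnings, msg)
  }

  # Step 1: Guinier analysis of the mixture
  gfit <- guinier_fit(iexp, qRg_max = cfg$qRg_max)
  qual <- guinier_quality(iexp, gfit)
  if (qual$upturn && !cfg$allow_upturn)
    stop("low-q upturn detected: visible aggregation, further purification needed (or set allow_upturn)")

  # Steps 2-3: forward-intensity split from the AUC fractions
  fwd <- monomer_forward_intensity(conc * gfit$I0, conc, components)
  i1_0 <- fwd$i1_0

  # Steps 4-5A, two passes: q* from apparent Rg first, then from refined Rg1
  Rg_ref <- gfit$Rg
  res <- NULL
  for (pass in 1:2) {
    q_star <- critical_q(Rg_ref)
    i1h <- assign_high_q(iexp, q_star)
    conn <- connect_low_q(i1_0, i1h, q_star, q_low = iexp$q,
                          i1_0_err = fwd$t1 * gfit$I0_err / (fwd$c1 / conc))
    warnings <- union(warnings, conn$warnings)
    res <- refine_monomer(conn$profile, i1_0, conn$q_c,
                          qRg_max_ext = cfg$qRg_max_ext, order = cfg$order,
                          tol = cfg$tol, max_iter = cfg$max_iter)
    Rg_ref <- res$Rg1
  }
  Rg1 <- res$Rg1
  q_star <- min(critical_q(Rg1), conn$q_c)

  # Debye-model systematic bound on [q*, q_c]
  model <- oligomer_model(geometry = cfg$geometry,
                          j_max = max(4L, max(components$j)), d = cfg$d)
  bound <- max_deviation(iexp, components, model, q_from = q_star,
                         Rg1 = Rg1)

  # aggregate residual on the measured grid: c_a i_a = c i_exp - c1 i1
  i1_on_grid <- regrid(res$profile,
                       iexp$q[iexp$q >= min(res$profile$q) &
                                iexp$q <= max(res$profile$q)])
  qa <- i1_on_grid$q
  ia <- conc * iexp$intensity[match(qa, iexp$q)] -
    fwd$c1 * i1_on_grid$intensity
  sa <- sqrt((conc * iexp$sigma[match(qa, iexp$q)])^2 +
               (fwd$c1 * i1_on_grid$sigma)^2)
  aggregate_intensity <- scattering_profile(
    qa, ia, sa, label = paste0(i_exp$label, " [aggregate c_a*i_a]"))

  structure(list(
    i1 = res$profile, i1_0 = i1_0, Rg1 = Rg1, Rg1_err = res$Rg1_err,
    t1 = fwd$t1, q_star = q_star, q_c = conn$q_c,
    aggregate_intensity = aggregate_intensity,
    model_bound = bound, mixture_fit = gfit, quality = qual,
    concentration = conc, c1 = fwd$c1,
    iterations = res$iterations, warnings = warnings),
    class = "monomer_extraction_result")
}

#' @export
print.monomer_extraction_result <- function(x, ...) {
  cat("<monomer_extraction_result>\n")
  cat(sprintf("  t1 = %.4f  (monomer share of forward scattering)\n", x$t1))
  cat(sprintf("  i1(0) = %.6g per mg/mL\n", x$i1_0))
  cat(sprintf("  Rg1 = %.3f +/- %.3f A\n", x$Rg1, x$Rg1_err))
  cat(sprintf("  q* = %.5f  q_c = %.5f 1/A\n", x$q_star, x$q_c))
  cat(sprintf("  Debye-model bound on [q*, ...]: %.2f%% (worst geometry)\n",
              100 * x$model_bound$worst))
  cat(sprintf("  refinement iterations: %d\n", x$iterations))
  if (length(x$warnings))
    cat("  warnings:\n", paste0("   - ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Flatten a monomer-extraction result to a named list (for JSON reports)
#' @param result A `monomer_extraction_result`.
#' @return Named list of scalars and the warning strings.
#' @export
extraction_report <- function(result) {
  stopifnot(inherits(result, "monomer_extraction_result"))
  list(t1 = result$t1, i1_0 = result$i1_0,
       Rg1 = result$Rg1, Rg1_err = result$Rg1_err,
       q_star = result$q_star, q_c = result$q_c,
       model_bound_linear = result$model_bound$linear,
       model_bound_close_packed = result$model_bound$close_packed,
       apparent_Rg = result$mixture_fit$Rg,
       iterations = result$iterations,
       warnings = result$warnings)
}
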