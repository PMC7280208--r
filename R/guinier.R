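#' Guinier fit of a scattering profile
#'
#' Weighted linear least squares of ln I versus q^2 over a self-consistent
#' low-q window: ln I(q) = ln I(0) - (q Rg)^2 / 3. Weights are 1/sigma_lnI^2
#' with sigma_lnI = sigma/I. The window is chosen iteratively so that
#' q_max * Rg <= `qRg_max`: fit, recompute the limit from the fitted Rg,
#' refit, until the point set is stable (at most 20 iterations).
#'
#' @param profile A [scattering_profile].
#' @param qRg_max Upper limit of q*Rg for the fit window (default 1.3, the
#'   usual convention for globular particles).
#' @param min_points Minimum number of points in the window (default 5).
#' @return An object of class `guinier_result`: list with `I0`, `Rg`,
#'   `I0_err`, `Rg_err`, `q_window`, `chi2_reduced`, `n_points`, `A4`
#'   (NA for the plain fit), plus the window indices and standardized
#'   residuals used by [guinier_quality()].
#' @export
guinier_fit <- function(profile, qRg_max = 1.3, min_points = 5L) {
  stopifnot(inherits(profile, "scattering_profile"))
  q <- profile$q; I <- profile$intensity; s <- profile$sigma
  usable <- which(is.finite(I) & I > 0)
  if (length(usable) < min_points)
    stop("no Guinier region: fewer than ", min_points, " positive points")
  # initial window: points still above ~exp(-1.3^2/3) of the forward value,
  # i.e. the region a Guinier law with q Rg <= 1.3 would span
  win <- usable[I[usable] > 0.55 * max(I[usable])]
  if (length(win) < max(10L, min_points))
    win <- usable[seq_len(min(length(usable), max(10L, min_points)))]
  seen <- list()
  for (iter in seq_len(20L)) {
    fit <- .guinier_lm(q[win], I[win], s[win])
    q_lim <- qRg_max / fit$Rg
    new_win <- usable[q[usable] <= q_lim]
    if (length(new_win) < min_points)
      new_win <- usable[seq_len(min_points)]
    # stable window, or a revisited one (limit cycle): accept current fit
    if (identical(new_win, win) ||
        any(vapply(seen, identical, logical(1), y = new_win)))
      return(.guinier_result(fit, q, win, profile))
    seen[[length(seen) + 1L]] <- win
    win <- new_win
  }
  stop("no Guinier region: fit window did not stabilize in 20 iterations")
}

# weighted lm of ln I ~ q^2; errors from the fit covariance
.guinier_lm <- function(q, I, s) {
  x <- q^2
  y <- log(I)
  w <- (I / s)^2
  fm <- stats::lm(y ~ x, weights = w)
  co <- stats::coef(fm)
  slope <- co[[2L]]
  if (!is.finite(slope) || slope >= 0)
    stop("no Guinier region: non-negative slope of ln I vs q^2")
  Rg <- sqrt(-3 * slope)
  sm <- summary(fm)
  se <- sm$coefficients[, "Std. Error"]
  n <- length(y)
  # lm rescales weights; chi2 against the absolute sigma_lnI:
  chi2 <- sum(w * stats::residuals(fm)^2) / max(n - 2L, 1L)
  # lm's se already includes the sqrt(chi2) scaling (dispersion estimated)
  list(I0 = exp(co[[1L]]), Rg = Rg,
       I0_err = exp(co[[1L]]) * se[[1L]],
       Rg_err = 3 * se[[2L]] / (2 * Rg),
       chi2_reduced = chi2, n = n,
       residuals_std = stats::residuals(fm) * sqrt(w),
       A4 = NA_real_)
}

.guinier_result <- function(fit, q, win, profile) {
  structure(list(I0 = fit$I0, Rg = fit$Rg,
                 I0_err = fit$I0_err, Rg_err = fit$Rg_err,
                 q_window = c(q[min(win)], q[max(win)]),
                 chi2_reduced = fit$chi2_reduced,
                 n_points = fit$n, A4 = fit$A4,
                 poly_coef = fit$poly_coef,
                 window_idx = win,
                 residuals_std = fit$residuals_std,
                 label = profile$label),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat("<guinier_result>", if (nzchar(x$label)) x$label else "", "\n")
  cat(sprintf("  I(0) = %.6g +/- %.2g\n", x$I0, x$I0_err))
  cat(sprintf("  Rg   = %.4f +/- %.3f A\n", x$Rg, x$Rg_err))
  cat(sprintf("  window q in [%.4g, %.4g] (%d pts), chi2_red = %.3g\n",
              x$q_window[1L], x$q_window[2L], x$n_points, x$chi2_reduced))
  if (is.finite(x$A4)) cat(sprintf("  A4 = %.4g\n", x$A4))
  invisible(x)
}

#' Extended Guinier fit
#'
#' Fits the polynomial extension of the Guinier law,
#' ln I(q) = ln I(0) - (q Rg)^2/3 + A4 (q Rg)^4 (+ higher even terms for
#' `order` > 2), which tracks globular form factors to a wider window than
#' the plain Guinier law (default q*Rg <= 2.0). The fit is linear in the
#' coefficients of q^2, q^4, ...; Rg is read off the q^2 coefficient and the
#' shape coefficients are reported relative to (q Rg)^2 powers. `I0_fixed`
#' constrains the intercept, which is how the monomer-extraction refinement
#' anchors the fit to the AUC-derived forward intensity.
#'
#' @param profile A [scattering_profile].
#' @param order Number of even polynomial terms in q (default 2: q^2 and q^4).
#'   `order = 1` reduces exactly to the plain Guinier model.
#' @param qRg_max_ext Window limit on q*Rg (default 2.0).
#' @param I0_fixed Optional fixed forward intensity; if given, ln I0 is not a
#'   free parameter.
#' @param min_points Minimum points in the window.
#' @return A `guinier_result` (see [guinier_fit()]); element `A4` holds the
#'   dimensionless 4th-order shape coefficient (0 for a pure Gaussian decay).
#' @export
extended_guinier_fit <- function(profile, order = 2L, qRg_max_ext = 2.0,
                                 I0_fixed = NULL, min_points = 5L) {
  stopifnot(inherits(profile, "scattering_profile"), order >= 1L)
  q <- profile$q; I <- profile$intensity; s <- profile$sigma
  usable <- which(is.finite(I) & I > 0)
  need <- max(min_points, order + 2L)
  if (length(usable) < need)
    stop("no Guinier region: fewer than ", need, " positive points")
  # initial window: down to ~exp(-4/3) of the forward value (q Rg <= 2)
  win <- usable[I[usable] > 0.26 * max(I[usable])]
  if (length(win) < max(10L, need))
    win <- usable[seq_len(min(length(usable), max(10L, need)))]
  seen <- list()
  for (iter in seq_len(20L)) {
    fit <- .ext_guinier_lm(q[win], I[win], s[win], order, I0_fixed)
    q_lim <- qRg_max_ext / fit$Rg
    new_win <- usable[q[usable] <= q_lim]
    if (length(new_win) < need) new_win <- usable[seq_len(need)]
    if (identical(new_win, win) ||
        any(vapply(seen, identical, logical(1), y = new_win)))
      return(.guinier_result(fit, q, win, profile))
    seen[[length(seen) + 1L]] <- win
    win <- new_win
  }
  stop("no Guinier region: fit window did not stabilize in 20 iterations")
}

.ext_guinier_lm <- function(q, I, s, order, I0_fixed) {
  y <- log(I)
  w <- (I / s)^2
  X <- outer(q^2, seq_len(order), `^`)   # q^2, q^4, ...
  colnames(X) <- paste0("p", seq_len(order))
  if (is.null(I0_fixed)) {
    fm <- stats::lm(y ~ X, weights = w)
    co <- stats::coef(fm)
    a0 <- co[[1L]]; b <- co[[2L]]
    se <- summary(fm)$coefficients[, "Std. Error"]
    I0 <- exp(a0); I0_err <- I0 * se[[1L]]; b_se <- se[[2L]]
  } else {
    y0 <- y - log(I0_fixed)
    fm <- stats::lm(y0 ~ X - 1, weights = w)
    co <- stats::coef(fm)
    b <- co[[1L]]
    se <- summary(fm)$coefficients[, "Std. Error"]
    I0 <- I0_fixed; I0_err <- 0; b_se <- se[[1L]]
  }
  if (!is.finite(b) || b >= 0)
    stop("no Guinier region: non-negative slope of ln I vs q^2")
  Rg <- sqrt(-3 * b)
  cq4 <- if (order >= 2L) co[[if (is.null(I0_fixed)) 3L else 2L]] else 0
  n <- length(y)
  npar <- order + is.null(I0_fixed)
  chi2 <- sum(w * stats::residuals(fm)^2) / max(n - npar, 1L)
  poly_coef <- if (is.null(I0_fixed)) co[-1L] else co
  list(I0 = I0, Rg = Rg, I0_err = I0_err,
       Rg_err = 3 * b_se / (2 * Rg),
       chi2_reduced = chi2, n = n,
       residuals_std = stats::residuals(fm) * sqrt(w),
       A4 = cq4 / Rg^4, poly_coef = unname(poly_coef))
}

#' Guinier-fit diagnostics and low-q upturn detection
#'
#' Inspects the standardized residuals of a Guinier fit for the systematic
#' positive low-q excess characteristic of aggregate contamination: among the
#' lowest 20% of window points (at least 3), the upturn flag is raised when
#' the residuals are predominantly positive and their mean is significantly
#' above zero. A Wald-Wolfowitz-style count of sign runs over the whole
#' window is also reported (too few runs indicates structured misfit).
#'
#' @param profile The fitted [scattering_profile].
#' @param result The [guinier_fit()] result for it.
#' @return A list: `upturn` (logical), `frac_positive_lowq`, `mean_z_lowq`,
#'   `n_lowq`, `n_runs`, `n_runs_expected`, and the standardized residual
#'   vector `z`.
#' @export
guinier_quality <- function(profile, result) {
  stopifnot(inherits(result, "guinier_result"))
  z <- result$residuals_std
  n <- length(z)
  m <- max(3L, ceiling(0.2 * n))
  zl <- z[seq_len(min(m, n))]
  frac_pos <- mean(zl > 0)
  mean_z <- mean(zl)
  # mean of m standard normals has sd 1/sqrt(m); require > 3 sd and
  # predominance of positive signs
  upturn <- (mean_z * sqrt(length(zl)) > 3) && frac_pos >= 0.8
  sgn <- sign(z[z != 0])
  n_runs <- if (length(sgn) > 1L) 1L + sum(diff(sgn) != 0) else length(sgn)
  np <- sum(sgn > 0); nm <- sum(sgn < 0)
  runs_exp <- if (np + nm > 0) 1 + 2 * np * nm / (np + nm) else 0
  list(upturn = upturn, frac_positive_lowq = frac_pos,
       mean_z_lowq = mean_z, n_lowq = length(zl),
       n_runs = n_runs, n_runs_expected = runs_exp, z = z)
}

#' Flatten a Guinier result to a named vector
#' @param result A `guinier_result`.
#' @return Named numeric vector (I0, Rg, errors, window, chi2, n).
#' @export
guinier_report <- function(result) {
  stopifnot(inherits(result, "guinier_result"))
  c(I0 = result$I0, I0_err = result$I0_err,
    Rg = result$Rg, Rg_err = result$Rg_err,
    q_min = result$q_window[1L], q_max = result$q_window[2L],
    chi2_reduced = result$chi2_reduced, n_points = result$n_points)
}
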