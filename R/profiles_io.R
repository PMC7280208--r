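#' Construct a scattering profile
#'
#' A `scattering_profile` holds one reduced 1-D small-angle scattering curve:
#' the scattering-vector magnitudes `q` (in 1/Angstrom), the intensity `I(q)`
#' (absolute cm^-1 or consistent arbitrary units), and its 1-sigma
#' uncertainties, together with the total mass concentration of the solution.
#'
#' @param q Numeric vector of scattering-vector magnitudes \[1/Angstrom\];
#'   must be positive and strictly increasing.
#' @param intensity Numeric vector of intensities, same length as `q`.
#' @param sigma Numeric vector of 1-sigma uncertainties, same length and scale
#'   as `intensity`; must be positive wherever `intensity` is finite.
#' @param concentration Optional total mass concentration c \[mg/mL\].
#' @param label Free-text label.
#' @return An object of class `scattering_profile`: a list with elements
#'   `q`, `intensity`, `sigma`, `concentration`, `label`.
#' @export
scattering_profile <- function(q, intensity, sigma,
                               concentration = NULL, label = "") {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  sigma <- as.numeric(sigma)
  if (length(q) != length(intensity) || length(q) != length(sigma))
    stop("q, intensity and sigma must have equal length")
  if (length(q) < 1L)
    stop("a scattering profile needs at least 1 point")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be finite and positive")
  if (any(diff(q) <= 0))
    stop("q must be strictly increasing")
  if (any(is.finite(intensity) & (!is.finite(sigma) | sigma <= 0)))
    stop("sigma must be positive wherever intensity is finite")
  if (!is.null(concentration)) {
    concentration <- as.numeric(concentration)
    if (length(concentration) != 1L || !is.finite(concentration) ||
        concentration <= 0)
      stop("concentration must be a single positive number [mg/mL]")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 concentration = concentration, label = as.character(label)),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat("<scattering_profile>", if (nzchar(x$label)) x$label else "", "\n")
  cat(sprintf("  %d points, q in [%.4g, %.4g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  if (!is.null(x$concentration))
    cat(sprintf("  concentration: %.4g mg/mL\n", x$concentration))
  invisible(x)
}

#' @export
as.data.frame.scattering_profile <- function(x, ...) {
  data.frame(q = x$q, intensity = x$intensity, sigma = x$sigma)
}

#' Per-mass intensity of a profile
#'
#' Divides intensity and sigma by the stored total mass concentration, giving
#' i(q) = I(q)/c. If no concentration is stored the profile is returned
#' unchanged (treated as already per-mass).
#'
#' @param profile A [scattering_profile].
#' @return A `scattering_profile` with unit concentration semantics
#'   (`concentration = NULL`).
#' @export
per_mass <- function(profile) {
  stopifnot(inherits(profile, "scattering_profile"))
  c0 <- profile$concentration
  if (is.null(c0)) return(profile)
  scattering_profile(profile$q, profile$intensity / c0, profile$sigma / c0,
                     concentration = NULL, label = profile$label)
}

#' Read a 3-column scattering profile
#'
#' Parses the de facto ATSAS-style `.dat` text format: at least three numeric
#' columns (q, I, sigma), separated by any mix of whitespace and commas.
#' Lines starting with `#` and lines whose tokens are not numeric (headers,
#' footers) are skipped. Rows with non-finite intensity are dropped with a
#' warning reporting the count.
#'
#' @param path Path to the text file.
#' @param concentration Optional total mass concentration c \[mg/mL\].
#' @param label Label; defaults to the file name.
#' @return A [scattering_profile].
#' @export
read_profile <- function(path, concentration = NULL,
                         label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(strsplit(lines, "[,[:space:]]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    if (length(tok) < 3L) return(NULL)
    val <- suppressWarnings(as.numeric(tok[1:3]))
    if (is.na(val[1L]) || is.na(val[3L])) return(NULL)  # non-numeric header
    val
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 2L)
    stop("malformed input: fewer than 2 valid (q, I, sigma) rows in ", path)
  m <- do.call(rbind, rows)
  bad <- !is.finite(m[, 2L])
  if (any(bad)) {
    message(sum(bad), " row(s) with non-finite intensity dropped from ", path)
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 2L)
    stop("malformed input: fewer than 2 finite rows in ", path)
  if (any(diff(m[, 1L]) <= 0))
    stop("ordering error: q is not strictly increasing in ", path)
  scattering_profile(m[, 1L], m[, 2L], m[, 3L],
                     concentration = concentration, label = label)
}

#' Write a scattering profile as 3-column text
#'
#' Values are written with 17 significant digits so that a read/write/read
#' round trip reproduces the profile to machine precision.
#'
#' @param profile A [scattering_profile].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "scattering_profile"))
  hdr <- c(paste0("# ", profile$label),
           if (!is.null(profile$concentration))
             sprintf("# concentration_mg_per_mL: %.17g",
                     profile$concentration),
           "# q[1/A] I sigma")
  body <- sprintf("%.17g %.17g %.17g",
                  profile$q, profile$intensity, profile$sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct an AUC component table
#'
#' Holds the species list derived from a sedimentation-velocity c(s) analysis:
#' per species the aggregation number j (1 = monomer, 2 = dimer, ...) and its
#' weight fraction of the total mass concentration. Fractions must sum to 1;
#' with `normalize = TRUE` they are rescaled (preserving ratios) provided the
#' raw sum lies in \[0.98, 1.02\], or unconditionally if `values_are`
#' is `"concentration"` (mass concentrations, e.g. c(s) peak areas).
#'
#' @param j Integer vector of aggregation numbers, unique, >= 1.
#' @param weight_fraction Numeric weight fractions (or mass concentrations if
#'   `values_are = "concentration"`).
#' @param s20w Optional sedimentation coefficients \[S\].
#' @param mass Optional molecular masses \[Da\].
#' @param normalize Rescale fractions to sum to exactly 1 (see Details).
#' @param values_are Either `"fraction"` or `"concentration"`.
#' @return An object of class `component_table`: a data.frame with columns
#'   `j`, `weight_fraction` and optionally `s20w`, `mass`.
#' @export
component_table <- function(j, weight_fraction, s20w = NULL, mass = NULL,
                            normalize = TRUE,
                            values_are = c("fraction", "concentration")) {
  values_are <- match.arg(values_are)
  j <- as.integer(j)
  w <- as.numeric(weight_fraction)
  if (length(j) != length(w) || length(j) < 1L)
    stop("j and weight_fraction must be non-empty and of equal length")
  if (anyDuplicated(j)) stop("duplicate aggregation numbers j")
  if (any(j < 1L)) stop("aggregation numbers j must be >= 1")
  if (any(!is.finite(w) | w < 0)) stop("fractions must be finite and >= 0")
  s <- sum(w)
  if (values_are == "concentration") {
    if (s <= 0) stop("total concentration must be positive")
    w <- w / s
  } else if (normalize) {
    if (s < 0.98 || s > 1.02)
      stop(sprintf("weight fractions sum to %.4g, outside [0.98, 1.02]", s))
    w <- w / s
  } else if (abs(s - 1) > 1e-6) {
    stop(sprintf("weight fractions sum to %.8g, not 1", s))
  }
  out <- data.frame(j = j, weight_fraction = w)
  if (!is.null(s20w)) out$s20w <- as.numeric(s20w)
  if (!is.null(mass)) out$mass <- as.numeric(mass)
  out <- out[order(out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("component_table", "data.frame")
  out
}

#' Read an AUC component table from CSV
#'
#' Expects a header `j,weight_fraction[,s20w,mass]` or
#' `j,concentration[,s20w,mass]`. A `concentration` column (mass
#' concentrations, mg/mL) is normalized to weight fractions on read; a
#' `weight_fraction` column must already sum to 1 within \[0.98, 1.02\].
#'
#' @param path Path to the CSV file.
#' @return A [component_table].
#' @export
read_components <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!"j" %in% names(df)) stop("component table needs a column 'j'")
  wcol <- intersect(c("weight_fraction", "concentration", "c"), names(df))
  if (length(wcol) == 0L)
    stop("component table needs 'weight_fraction' or 'concentration'")
  wcol <- wcol[1L]
  component_table(
    df$j, df[[wcol]],
    s20w = if ("s20w" %in% names(df)) df$s20w,
    mass = if ("mass" %in% names(df)) df$mass,
    values_are = if (wcol == "weight_fraction") "fraction" else "concentration")
}

#' Write a component table as CSV
#' @param components A [component_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_components <- function(components, path) {
  stopifnot(inherits(components, "component_table"))
  df <- as.data.frame(unclass(components))
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total aggregate weight fraction (j >= 2)
#' @param components A [component_table].
#' @return Summed weight fraction of all species with j >= 2.
#' @export
aggregate_fraction <- function(components) {
  stopifnot(inherits(components, "component_table"))
  sum(components$weight_fraction[components$j >= 2L])
}

#' Interpolate a profile onto a new q-grid
#'
#' Linear interpolation of intensity and uncertainty in (q, I). Uncertainties
#' at interpolated points are inflated to no less than the larger of the two
#' neighbouring sigmas (interpolation cannot reduce uncertainty); points that
#' coincide with the original grid keep their exact values, so regridding a
#' profile onto its own grid is the identity. No extrapolation is performed.
#'
#' @param profile A [scattering_profile].
#' @param q_new Target q values, within `range(profile$q)`.
#' @param mode Interpolation mode; only `"linear"` is implemented.
#' @return A [scattering_profile] on `q_new`.
#' @export
regrid <- function(profile, q_new, mode = "linear") {
  stopifnot(inherits(profile, "scattering_profile"))
  mode <- match.arg(mode, "linear")
  q_new <- sort(as.numeric(q_new))
  q <- profile$q
  if (min(q_new) < min(q) || max(q_new) > max(q))
    stop(sprintf("range error: q_new must lie within [%.6g, %.6g]",
                 min(q), max(q)))
  I_new <- stats::approx(q, profile$intensity, xout = q_new)$y
  s_lin <- stats::approx(q, profile$sigma, xout = q_new)$y
  idx <- findInterval(q_new, q, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(q) - 1L)
  s_nbr <- pmax(profile$sigma[idx], profile$sigma[idx + 1L])
  sig_new <- pmax(s_lin, s_nbr)
  on_grid <- q_new %in% q
  if (any(on_grid)) {
    pos <- match(q_new[on_grid], q)
    I_new[on_grid] <- profile$intensity[pos]
    sig_new[on_grid] <- profile$sigma[pos]
  }
  scattering_profile(q_new, I_new, sig_new,
                     concentration = profile$concentration,
                     label = profile$label)
}

#' Construct a sedimentation-equilibrium scan
#'
#' One radial absorbance scan from SE-AUC: absorbance a(r) versus radius at a
#' single rotor speed and loading.
#'
#' @param radius Radial positions \[cm\], strictly increasing.
#' @param absorbance Absorbance values \[AU\], same length.
#' @param rpm Rotor speed \[revolutions per minute\], > 0.
#' @param loading Named numeric `c(A = , B = )`: nominal molar loading
#'   concentrations \[uM\].
#' @param temperature Absolute temperature \[K\].
#' @return An object of class `se_scan`.
#' @export
se_scan <- function(radius, absorbance, rpm, loading,
                    temperature = 298.15) {
  radius <- as.numeric(radius); absorbance <- as.numeric(absorbance)
  if (length(radius) != length(absorbance) || length(radius) < 5L)
    stop("radius and absorbance must match and have >= 5 points")
  if (any(diff(radius) <= 0)) stop("radius must be strictly increasing")
  if (!is.finite(rpm) || rpm <= 0) stop("rpm must be positive")
  if (!all(c("A", "B") %in% names(loading)))
    stop("loading must be a named vector with elements A and B [uM]")
  structure(list(radius = radius, absorbance = absorbance, rpm = rpm,
                 loading = loading[c("A", "B")],
                 temperature = temperature),
            class = "se_scan")
}

#' @export
print.se_scan <- function(x, ...) {
  cat(sprintf(
    "<se_scan> %d points, r in [%.3f, %.3f] cm, %g rpm, [A]=%g [B]=%g uM\n",
    length(x$radius), min(x$radius), max(x$radius), x$rpm,
    x$loading[["A"]], x$loading[["B"]]))
  invisible(x)
}

#' Read sedimentation-equilibrium scans from a multi-section CSV
#'
#' The file holds one or more scans. Each scan starts with a line `scan`,
#' followed by `key,value` metadata lines (`rpm`, `loading_A`, `loading_B`,
#' `temperature`), a header `radius,absorbance`, and the data rows.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the scans file.
#' @return A list of [se_scan] objects.
#' @export
read_se_scans <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- which(tolower(lines) == "scan")
  if (length(starts) == 0L) stop("no 'scan' sections found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1L):ends[k]]
    meta <- list(temperature = 298.15)
    data_at <- which(tolower(block) == "radius,absorbance")[1L]
    if (is.na(data_at)) stop("scan ", k, ": missing 'radius,absorbance' header")
    for (ln in block[seq_len(data_at - 1L)]) {
      kv <- strsplit(ln, ",")[[1L]]
      meta[[tolower(trimws(kv[1L]))]] <- as.numeric(kv[2L])
    }
    m <- do.call(rbind, lapply(strsplit(block[(data_at + 1L):length(block)],
                                        ","), as.numeric))
    se_scan(m[, 1L], m[, 2L], rpm = meta$rpm,
            loading = c(A = meta$loading_a, B = meta$loading_b),
            temperature = meta$temperature)
  })
}

#' Write sedimentation-equilibrium scans to a multi-section CSV
#' @param scans A list of [se_scan] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_se_scans <- function(scans, path) {
  if (inherits(scans, "se_scan")) scans <- list(scans)
  out <- unlist(lapply(scans, function(s) {
    c("scan",
      sprintf("rpm,%.17g", s$rpm),
      sprintf("loading_A,%.17g", s$loading[["A"]]),
      sprintf("loading_B,%.17g", s$loading[["B"]]),
      sprintf("temperature,%.17g", s$temperature),
      "radius,absorbance",
      sprintf("%.17g,%.17g", s$radius, s$absorbance))
  }))
  writeLines(out, path)
  invisible(path)
}
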