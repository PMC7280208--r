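#' Define an oligomer geometry model
#'
#' Trace aggregates in a purified sample are modelled as compact or linear
#' homo-oligomers of j identical monomers with centre-to-centre contact
#' distance d between touching neighbours:
#' \describe{
#'   \item{linear}{collinear centres, pairwise distances |k - l| d}
#'   \item{close_packed}{maximally compact arrangements: touching pair
#'     (j = 2), equilateral triangle of side d (j = 3), regular tetrahedron
#'     of edge d (j = 4) — every pair at distance d}
#' }
#'
#' @param geometry `"close_packed"` or `"linear"`.
#' @param j_max Largest supported aggregation number (2..8; close-packed
#'   geometries are defined up to j = 4).
#' @param d Contact distance \[Angstrom\]; `NULL` to derive it from the
#'   monomer Rg at use time via [default_contact_distance()].
#' @return An object of class `oligomer_model`.
#' @export
oligomer_model <- function(geometry = c("close_packed", "linear"),
                           j_max = 4L, d = NULL) {
  geometry <- match.arg(geometry)
  j_max <- as.integer(j_max)
  if (j_max < 2L || j_max > 8L) stop("j_max must be in 2..8")
  if (geometry == "close_packed" && j_max > 4L)
    stop("close-packed geometries are defined for j <= 4")
  if (!is.null(d) && (!is.finite(d) || d <= 0))
    stop("contact distance d must be positive")
  structure(list(geometry = geometry, j_max = j_max, d = d),
            class = "oligomer_model")
}

#' Sphere-equivalent contact distance from the monomer Rg
#'
#' The diameter of the homogeneous sphere with the monomer's radius of
#' gyration: d = 2 sqrt(5/3) Rg1.
#'
#' @param Rg1 Monomer radius of gyration \[Angstrom\].
#' @return Contact distance \[Angstrom\].
#' @export
default_contact_distance <- function(Rg1) {
  stopifnot(is.finite(Rg1), Rg1 > 0)
  2 * sqrt(5 / 3) * Rg1
}

# resolve the model's contact distance, deriving it from Rg1 if unset
.model_d <- function(model, Rg1 = NULL) {
  if (!is.null(model$d)) return(model$d)
  if (is.null(Rg1))
    stop("model has no contact distance d; supply Rg1 to derive it")
  default_contact_distance(Rg1)
}

# pairwise centre-to-centre distances for a j-mer
.pair_distances <- function(j, geometry, d) {
  if (j == 1L) return(numeric(0))
  if (geometry == "linear") {
    idx <- utils::combn(j, 2L)
    return(abs(idx[1L, ] - idx[2L, ]) * d)
  }
  if (j > 4L) stop("unsupported geometry: close-packed j > 4")
  rep(d, j * (j - 1L) / 2L)  # pair/triangle/tetrahedron: all pairs touch
}

# sin(x)/x with series near 0 to avoid 0/0; preserves dim()
.sinc <- function(x) {
  out <- x
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 6 + x[small]^4 / 120
  out[!small] <- sin(x[!small]) / x[!small]
  out
}

#' Debye interference factor of a j-mer
#'
#' Orientation-averaged structure sum S_j(q) = j + 2 sum_\{k<l\}
#' sin(q d_kl)/(q d_kl) over all monomer pairs. S_j(0) = j^2.
#'
#' @param q Scattering vector magnitudes \[1/Angstrom\].
#' @param j Aggregation number.
#' @param model An [oligomer_model].
#' @param Rg1 Monomer Rg, used only if the model carries no fixed d.
#' @return Numeric vector S_j(q).
#' @export
structure_factor <- function(q, j, model, Rg1 = NULL) {
  stopifnot(inherits(model, "oligomer_model"))
  j <- as.integer(j)
  if (j < 1L) stop("j must be >= 1")
  if (j > model$j_max)
    stop("unsupported geometry: j = ", j, " exceeds j_max = ", model$j_max)
  if (j == 1L) return(rep(1, length(q)))
  dkl <- .pair_distances(j, model$geometry, .model_d(model, Rg1))
  j + 2 * rowSums(.sinc(outer(q, dkl)))
}

#' Per-mass scattering intensity of a j-mer
#'
#' Under the decoupling assumption (the oligomer is an assembly of neat
#' monomers with averaged orientations), i_j(q) = i_1(q) S_j(q) / j where
#' S_j is the Debye interference factor. The division by j converts to
#' per-unit-mass intensity, so i_j(0) = j i_1(0): forward scattering per
#' mass is proportional to the mass of the scatterer.
#'
#' @param i1 Monomer per-mass profile ([scattering_profile]).
#' @param j Aggregation number.
#' @param model An [oligomer_model].
#' @param Rg1 Monomer Rg, used only if the model carries no fixed d.
#' @return A [scattering_profile] with the j-mer per-mass intensity.
#' @export
oligomer_intensity <- function(i1, j, model, Rg1 = NULL) {
  stopifnot(inherits(i1, "scattering_profile"))
  if (any(i1$intensity <= 0))
    stop("monomer intensity must be positive")
  f <- structure_factor(i1$q, j, model, Rg1) / as.integer(j)
  scattering_profile(i1$q, i1$intensity * f, i1$sigma * f,
                     concentration = NULL,
                     label = sprintf("%s [j=%d %s]", i1$label, j,
                                     model$geometry))
}

#' Intensity ratio r(q) of the mixture to the monomer
#'
#' r(q) = \[sum_j w_j i_j(q)\] / i_1(q) with w_j the weight fractions and
#' i_j the Debye-model oligomer intensities. Under the decoupling model the
#' monomer profile cancels, so r depends only on the fractions and the
#' geometry: r(q) = sum_j w_j S_j(q)/j. r(0) = sum_j w_j j >= 1 and
#' r(q) -> 1 at high q, which is what licenses reading the high-angle part
#' of the measured curve as the monomer's.
#'
#' @param i1 Monomer per-mass profile (supplies the q grid; its scale cancels).
#' @param components A [component_table].
#' @param model An [oligomer_model].
#' @param Rg1 Monomer Rg, used only if the model carries no fixed d.
#' @return data.frame with columns `q` and `r`.
#' @export
intensity_ratio <- function(i1, components, model, Rg1 = NULL) {
  stopifnot(inherits(i1, "scattering_profile"),
            inherits(components, "component_table"))
  active <- components[components$weight_fraction > 0, , drop = FALSE]
  if (any(active$j > model$j_max))
    stop("component with j > j_max = ", model$j_max, " present")
  r <- rowSums(vapply(seq_len(nrow(active)), function(k) {
    active$weight_fraction[k] *
      structure_factor(i1$q, active$j[k], model, Rg1) / active$j[k]
  }, numeric(length(i1$q))))
  data.frame(q = i1$q, r = r)
}

#' High-q validity threshold q*
#'
#' The lowest q at which the mixture intensity approximates the monomer's:
#' q* = 1.0 / Rg1.
#'
#' @param Rg1 Monomer radius of gyration \[Angstrom\].
#' @return q* \[1/Angstrom\].
#' @export
critical_q <- function(Rg1) {
  stopifnot(is.finite(Rg1), Rg1 > 0)
  1.0 / Rg1
}

#' Maximum deviation of r(q) from unity above a threshold
#'
#' The model-bound systematic error incurred by identifying the measured
#' high-angle intensity with the monomer's: sup |r(q) - 1| on the grid
#' restricted to q >= `q_from`, evaluated for each oligomer geometry and as
#' the worst case over both.
#'
#' @param i1 Monomer per-mass profile (q grid).
#' @param components A [component_table].
#' @param model An [oligomer_model] (its `d`/`j_max` are used; the deviation
#'   is computed for both geometries regardless of `model$geometry`).
#' @param q_from Lower q limit, within the grid.
#' @param Rg1 Monomer Rg, used only if the model carries no fixed d.
#' @return List with `linear`, `close_packed`, `worst` (all max |r - 1|),
#'   and `q_from`.
#' @export
max_deviation <- function(i1, components, model, q_from, Rg1 = NULL) {
  keep <- i1$q >= q_from
  if (!any(keep)) stop("no grid points at q >= ", q_from)
  sub <- scattering_profile(i1$q[keep], i1$intensity[keep], i1$sigma[keep],
                            label = i1$label)
  dev <- vapply(c("linear", "close_packed"), function(g) {
    m <- oligomer_model(geometry = g, j_max = model$j_max, d = model$d)
    max(abs(intensity_ratio(sub, components, m, Rg1)$r - 1))
  }, numeric(1))
  list(linear = dev[["linear"]], close_packed = dev[["close_packed"]],
       worst = max(dev), q_from = q_from)
}

#' Export an r(q) curve as 2-column text
#' @param ratio data.frame from [intensity_ratio()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio <- function(ratio, path) {
  writeLines(c("# q[1/A] r", sprintf("%.17g %.17g", ratio$q, ratio$r)), path)
  invisible(path)
}
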