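# Evaluation layer: principal compressive stress (PCS) field, active
# load-carrying area, S1/S2 average stresses, the load share ratio LSR =
# S1/S2, percent change against the normal model, and the lesion-severity
# classifier.

#' Principal decomposition of a plane stress field
#'
#' Closed-form eigendecomposition of each element's in-plane 2x2 stress
#' tensor.  The PCS magnitude is `max(0, -sigma_min)`: the compressive
#' principal stress as a positive number, zero where the element is not in
#' compression.
#'
#' @param stress Element stress tibble from [element_stress()].
#' @return The input with columns added: principal values `s1 >= s2`,
#'   principal direction angle `dir_deg` (of the major principal axis,
#'   sign-free line field), and `pcs`.
#' @export
#' @examples
#' principal_decompose(tibble::tibble(sxx = 0, syy = 0, sxy = 2))[, c("s1", "s2", "pcs")]
principal_decompose <- function(stress) {
  ctr <- (stress$sxx + stress$syy) / 2
  rad <- sqrt(((stress$sxx - stress$syy) / 2)^2 + stress$sxy^2)
  stress$s1 <- ctr + rad
  stress$s2 <- ctr - rad
  stress$dir_deg <- atan2(2 * stress$sxy, stress$sxx - stress$syy) * 90 / pi
  stress$pcs <- pmax(0, -stress$s2)
  stress
}

#' Scalar stress measure used in region averages
#'
#' `"pcs"` is the principal-compressive-stress magnitude; `"vonmises"` the
#' von Mises equivalent stress including the plane-strain out-of-plane
#' component.
#'
#' @param stress Element stress tibble.
#' @param measure `"pcs"` or `"vonmises"`.
#' @return Numeric vector, one value per element.
#' @export
stress_measure <- function(stress, measure = c("pcs", "vonmises")) {
  measure <- match.arg(measure)
  if (measure == "pcs") {
    if (!("pcs" %in% names(stress))) stress <- principal_decompose(stress)
    stress$pcs
  } else {
    with(stress, sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) +
                        3 * sxy^2))
  }
}

# Area-weighted quantile (inverse of the weighted empirical cdf).
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= p)[1]]
}

# The active-area domain: the head's trabecular territory (everything inside
# the head disk except the cortical shell), because the principal compressive
# trabeculae are the structure whose loading the PCS field traces.  Meshes
# without tissue labels (benchmark domains) use the whole disk.
pcs_domain <- function(stress, head_radius) {
  inside <- sqrt(stress$cx^2 + stress$cy^2) <= head_radius
  if (all(is.na(stress$tissue))) inside
  else inside & stress$tissue != "cortical"
}

#' Reference PCS scale of a solved model
#'
#' The area-weighted 95th percentile of PCS over the head's trabecular
#' territory; the normal model at beta = 0 provides the reference scale for
#' all active-area thresholds.
#'
#' @param stress Element stress tibble (head geometry).
#' @param head_radius Head radius (mm); elements with centroid inside the
#'   head disk (and outside the cortical shell, when tissue labels are
#'   present) are used.
#' @return Scalar PCS value (MPa).
#' @export
pcs_reference <- function(stress, head_radius) {
  stress <- principal_decompose(stress)
  dom <- pcs_domain(stress, head_radius)
  weighted_quantile(stress$pcs[dom], stress$area[dom], 0.95)
}

#' Active (load-carrying) area fraction of the femoral head
#'
#' Fraction of the head's trabecular territory occupied by *living* bone
#' whose PCS is at least `tau_frac` times the reference scale (the normal
#' beta = 0 model's 95th-percentile PCS).  Necrotic tissue never counts as
#' active: a functioning load path requires living trabeculae, and under a
#' prescribed contact traction a dead wedge directly below the load still
#' transmits stress in series, so counting it would equate a dead column
#' with a functioning fan.  Shrinkage of this fraction quantifies the damage
#' to the compressive load-transfer path.
#'
#' @param stress Element stress tibble of the model under evaluation.
#' @param head_radius Head radius (mm).
#' @param reference_pcs Reference PCS scale from [pcs_reference()] of the
#'   normal beta = 0 model; a missing reference is a sequencing error.
#' @param tau_frac Threshold fraction of the reference scale.  The default
#'   0.3 puts the normal model's active fraction near one half, matching the
#'   extent of the compressive fan on a coronal section; far lower values
#'   saturate (nearly the whole section counts as active).
#' @return Area fraction in `[0, 1]`.
#' @export
active_area <- function(stress, head_radius, reference_pcs, tau_frac = 0.3) {
  if (missing(reference_pcs) || is.null(reference_pcs) || is.na(reference_pcs)) {
    stop("sequencing error: solve the NORMAL beta = 0 reference model first ",
         "and pass its pcs_reference()", call. = FALSE)
  }
  stress <- principal_decompose(stress)
  dom <- pcs_domain(stress, head_radius)
  a <- stress$area[dom]
  living <- is.na(stress$tissue[dom]) | stress$tissue[dom] != "necrotic"
  act <- living & stress$pcs[dom] >= tau_frac * reference_pcs
  sum(a[act]) / sum(a)
}

#' Load share ratio between the cortical column and trabecular corridor
#'
#' Area-weighted mean stress (PCS magnitude by default) over the elements
#' whose centroids lie in the S1 (subchondral cortical column) and S2
#' (trabecular stress-transfer corridor) masks, and their ratio
#' `LSR = S1_avg / S2_avg`.  Masks come from the intact anatomy so all
#' conditions are averaged over identical regions.
#'
#' @param stress Element stress tibble.
#' @param masks List with polygons `S1`, `S2` from [region_masks()].
#' @param measure Scalar stress measure, see [stress_measure()].
#' @return A one-row tibble: `S1_avg_MPa`, `S2_avg_MPa`, `LSR`.
#' @export
lsr <- function(stress, masks, measure = "pcs") {
  val <- stress_measure(stress, measure)
  in1 <- points_in_poly(stress$cx, stress$cy, masks$S1)
  in2 <- points_in_poly(stress$cx, stress$cy, masks$S2)
  if (!any(in1) || !any(in2)) {
    stop("configuration error: S1/S2 mask has empty intersection with the ",
         "mesh", call. = FALSE)
  }
  s1 <- sum(val[in1] * stress$area[in1]) / sum(stress$area[in1])
  s2 <- sum(val[in2] * stress$area[in2]) / sum(stress$area[in2])
  tibble::tibble(S1_avg_MPa = s1, S2_avg_MPa = s2, LSR = s1 / s2)
}

#' Percent change of a load share ratio against the normal reference
#'
#' @param lsr_lesion LSR of the lesioned model.
#' @param lsr_normal LSR of the normal model (must be positive).
#' @return Percent change, `100 (lsr_lesion - lsr_normal) / lsr_normal`.
#' @export
#' @examples
#' percent_change(1.5, 1.0)
percent_change <- function(lsr_lesion, lsr_normal) {
  if (any(lsr_normal <= 0)) {
    stop("domain error: reference LSR must be positive", call. = FALSE)
  }
  100 * (lsr_lesion - lsr_normal) / lsr_normal
}

jic_severity_order <- c("NORMAL", "A", "B", "C1", "C2")

#' Classify a model's damage pattern against the beta = 0 references
#'
#' Returns the label of the beta = 0 reference condition whose active-area
#' fraction is nearest the query's; ties break towards the healthier label.
#' This operationalises statements like "the stress pattern of Type B
#' transformed into Type A under abduction" as movement between
#' reference extents.
#'
#' @param active_fraction Active-area fraction of the query model.
#' @param reference Tibble with columns `condition` and
#'   `active_area_fraction` for all five beta = 0 conditions.
#' @return Character label.
#' @export
classify_pattern <- function(active_fraction, reference) {
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("sequencing error: beta = 0 reference table is empty", call. = FALSE)
  }
  ref <- reference[match(jic_severity_order, reference$condition), ]
  ref <- ref[!is.na(ref$condition), ]
  d <- abs(ref$active_area_fraction - active_fraction)
  # ref is in severity order; which.min takes the first (healthiest) on ties
  ref$condition[which.min(d)]
}
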