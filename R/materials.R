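# Tissue material properties.
#
# The model is isotropic linear elastic per tissue.  Default moduli are
# literature-typical bone values: cortical bone is roughly 17 GPa, trabecular
# bone of the proximal femur about 1 GPa at the continuum scale, and necrotic
# (dead, resorbing) bone an order of magnitude softer still.  They are the
# central free parameters of the model and are fully config-overridable.

#' Default tissue material table
#'
#' @param E_cortical,E_trabecular,E_necrotic Young's moduli in MPa.
#' @param nu Poisson ratio, shared by all tissues by default.
#' @return A tibble with columns `tissue`, `E`, `nu`.
#' @export
#' @examples
#' material_table()
material_table <- function(E_cortical = 17000,
                           E_trabecular = 1000,
                           E_necrotic = 100,
                           nu = 0.3) {
  tbl <- tibble::tibble(
    tissue = c("cortical", "trabecular", "necrotic"),
    E = c(E_cortical, E_trabecular, E_necrotic),
    nu = rep(nu, length.out = 3)
  )
  validate_material_table(tbl)
  tbl
}

validate_material_table <- function(tbl) {
  need <- c("cortical", "trabecular", "necrotic")
  if (!all(need %in% tbl$tissue)) {
    stop("material table must cover tissues: ",
         paste(setdiff(need, tbl$tissue), collapse = ", "), call. = FALSE)
  }
  if (any(tbl$E <= 0)) stop("Young's modulus E must be > 0", call. = FALSE)
  if (any(tbl$nu < 0 | tbl$nu >= 0.5)) {
    stop("Poisson ratio nu must satisfy 0 <= nu < 0.5", call. = FALSE)
  }
  invisible(tbl)
}

#' Assign per-element tissue labels and elastic constants
#'
#' Each element is labelled by the tissue region containing its centroid and
#' the elastic constants are looked up in the material table.
#'
#' @param mesh A `coxa_mesh` of the geometry.
#' @param geom The `coxa_geometry` the mesh discretises.
#' @param table Material table as from [material_table()].
#' @return A tibble with one row per element: `element`, `tissue`, `E`, `nu`,
#'   `area`.
#' @export
#' @examples
#' geom <- build_outline(geometry_params())
#' mesh <- triangulate(geom, h = 2.5)
#' mats <- assign_materials(mesh, geom)
#' table(mats$tissue)
assign_materials <- function(mesh, geom, table = material_table()) {
  stopifnot(inherits(mesh, "coxa_mesh"), inherits(geom, "coxa_geometry"))
  validate_material_table(table)
  cen <- mesh_centroids(mesh)
  lab <- region_label(geom, cen[, 1], cen[, 2])
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1]
    stop(sprintf(
      "tagging error: element %d centroid (%.3f, %.3f) lies in no tissue region (mesh nonconforming)",
      bad, cen[bad, 1], cen[bad, 2]
    ), call. = FALSE)
  }
  i <- match(lab, table$tissue)
  tibble::tibble(
    element = seq_len(nrow(mesh$tri)),
    tissue = lab,
    E = table$E[i],
    nu = table$nu[i],
    area = mesh_areas(mesh)
  )
}
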