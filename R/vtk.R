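# Field export: VTK legacy unstructured grid (ASCII) and OFF, for visual
# inspection in ParaView and friends.

#' Write a mesh with optional fields as a VTK legacy file
#'
#' @param mesh A `coxa_mesh`.
#' @param file Output path.
#' @param point_data Named list of per-node fields; an n x 2 matrix is
#'   written as a 3-component vector field (z = 0), a vector as scalars.
#' @param cell_data Named list of per-element scalar fields.
#' @return Invisibly, the file path.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tri)
  con <- file(file, open = "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "coxafem unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.9g %.9g 0", v[, 1], v[, 2]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", v), con)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  invisible(file)
}

#' Write a mesh in OFF format
#'
#' @param mesh A `coxa_mesh`.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_off <- function(mesh, file) {
  con <- file(file, open = "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(mesh$nodes), nrow(mesh$tri))),
             con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  invisible(file)
}

#' Write geometry region polygons as WKT text
#'
#' @param geom A `coxa_geometry`.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_geometry_wkt <- function(geom, file) {
  lines <- c(paste0("outline\t", polygon_wkt(geom$outline)))
  for (nm in names(geom$regions)) {
    polys <- geom$regions[[nm]]
    if (length(polys)) {
      lines <- c(lines, paste0(nm, "\t", polygon_wkt(polys)))
    }
  }
  writeLines(lines, file)
  invisible(file)
}
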