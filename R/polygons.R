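# Small planar-polygon toolkit used by the geometry layer.
#
# Polygons are plain two-column matrices (x, y), vertices in order, not closed
# (first vertex is not repeated).  Counter-clockwise orientation has positive
# signed area.

#' Signed area of a polygon (shoelace formula)
#'
#' @param poly Two-column numeric matrix of vertices, open ring.
#' @return Signed area; positive for counter-clockwise orientation.
#' @keywords internal
poly_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Centroid of a simple polygon
#' @inheritParams poly_area
#' @return Length-2 numeric (x, y).
#' @keywords internal
poly_centroid <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Test points against a polygon
#'
#' Vectorised point-in-polygon membership (boundary points count as inside).
#'
#' @param px,py Numeric vectors of query coordinates.
#' @param poly Polygon matrix.
#' @return Logical vector.
#' @keywords internal
points_in_poly <- function(px, py, poly) {
  if (length(px) == 0L) return(logical(0))
  res <- pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = TRUE)
  as.logical(res)
}

#' Clip a polygon by a convex polygon (Sutherland-Hodgman)
#'
#' @param subject Polygon matrix to be clipped (any simple polygon).
#' @param clip Convex polygon matrix, counter-clockwise.
#' @return Clipped polygon matrix, possibly with zero rows.
#' @keywords internal
clip_convex <- function(subject, clip) {
  if (poly_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[k, ]
    b <- clip[if (k == nc) 1L else k + 1L, ]
    ex <- b[1] - a[1]
    ey <- b[2] - a[2]
    # signed distance: > 0 means inside (left of edge for CCW clip polygon)
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1], 1L)
    keep_pts <- vector("list", n)
    for (i in seq_len(n)) {
      j <- nxt[i]
      si <- side[i]
      sj <- side[j]
      pts <- NULL
      if (si >= 0) pts <- rbind(pts, out[i, ])
      if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
        t <- si / (si - sj)
        pts <- rbind(pts, out[i, ] + t * (out[j, ] - out[i, ]))
      }
      keep_pts[[i]] <- pts
    }
    out <- do.call(rbind, keep_pts)
    if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  }
  # drop consecutive duplicates
  if (nrow(out) > 1L) {
    j <- c(seq_len(nrow(out))[-1], 1L)
    d <- sqrt((out[, 1] - out[j, 1])^2 + (out[, 2] - out[j, 2])^2)
    out <- out[d > 1e-12, , drop = FALSE]
  }
  out
}

#' Polygon approximating a circular arc annular sector
#'
#' Builds the region `r_in <= r <= r_out`, `a1 <= theta <= a2` (degrees).
#' With r_in = 0 the sector degenerates to a pie slice.
#'
#' @param r_in,r_out Inner and outer radii.
#' @param a1,a2 Angular limits in degrees, counter-clockwise.
#' @param n Number of arc subdivisions.
#' @param center Circle centre.
#' @return Polygon matrix, counter-clockwise.
#' @keywords internal
annular_sector <- function(r_in, r_out, a1, a2, n = 64L, center = c(0, 0)) {
  th <- seq(a1, a2, length.out = n + 1L) * pi / 180
  outer <- cbind(center[1] + r_out * cos(th), center[2] + r_out * sin(th))
  if (r_in <= 0) {
    rbind(center, outer)
  } else {
    inner <- cbind(center[1] + r_in * cos(rev(th)), center[2] + r_in * sin(rev(th)))
    rbind(outer, inner)
  }
}

#' Serialise polygons as WKT text
#'
#' @param polys A polygon matrix or list of polygon matrices.
#' @return Character vector of `POLYGON ((...))` strings.
#' @export
polygon_wkt <- function(polys) {
  if (is.matrix(polys)) polys <- list(polys)
  vapply(polys, function(p) {
    ring <- rbind(p, p[1, , drop = FALSE])
    coords <- paste(sprintf("%.9g %.9g", ring[, 1], ring[, 2]), collapse = ", ")
    sprintf("POLYGON ((%s))", coords)
  }, character(1))
}
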