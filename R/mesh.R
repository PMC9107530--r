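# Deterministic mapped triangulations.
#
# The proximal femur is meshed as a polar grid over the head disk joined to a
# transfinite-interpolation quad patch over the neck/shaft stem; both grids
# share the nodes on the head-stem junction arc, so the union is conforming.
# Rings and spokes are placed exactly on every material interface inside the
# head (outer surface, inner shell surface, lesion floor and flanks), so no
# head element straddles an interface.  The construction uses no random
# numbers: identical inputs give identical meshes.

new_mesh <- function(nodes, tri, boundary, h, extra = list()) {
  m <- c(list(nodes = nodes, tri = tri, boundary = boundary, h = h), extra)
  class(m) <- "coxa_mesh"
  m
}

#' @export
print.coxa_mesh <- function(x, ...) {
  cat("<coxa_mesh>", nrow(x$nodes), "nodes,", nrow(x$tri), "triangles, h =",
      x$h, "mm\n")
  cat("  boundary parts:", paste(unique(x$boundary$part), collapse = ", "), "\n")
  invisible(x)
}

#' Triangle areas of a mesh
#' @param mesh A `coxa_mesh`.
#' @return Numeric vector of element areas (all positive for a valid mesh).
#' @export
mesh_areas <- function(mesh) {
  n <- mesh$nodes
  t <- mesh$tri
  x1 <- n[t[, 1], 1]; y1 <- n[t[, 1], 2]
  x2 <- n[t[, 2], 1]; y2 <- n[t[, 2], 2]
  x3 <- n[t[, 3], 1]; y3 <- n[t[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Element centroids of a mesh
#' @param mesh A `coxa_mesh`.
#' @return Two-column matrix of centroid coordinates.
#' @export
mesh_centroids <- function(mesh) {
  n <- mesh$nodes
  t <- mesh$tri
  cbind(
    (n[t[, 1], 1] + n[t[, 2], 1] + n[t[, 3], 1]) / 3,
    (n[t[, 1], 2] + n[t[, 2], 2] + n[t[, 3], 2]) / 3
  )
}

# Merge a uniform subdivision of [lo, hi] with required break values: uniform
# points closer than 0.45 steps to a required value are dropped, required
# values inserted exactly.  Endpoints are kept.
merge_breaks <- function(lo, hi, step_target, required = numeric(0)) {
  n <- max(2L, round((hi - lo) / step_target))
  step <- (hi - lo) / n
  u <- seq(lo, hi, length.out = n + 1L)
  req <- sort(unique(required[required > lo + 1e-9 & required < hi - 1e-9]))
  for (r in req) u <- u[abs(u - r) > 0.45 * step | abs(u - lo) < 1e-12 | abs(u - hi) < 1e-12]
  sort(unique(c(u, req)))
}

# Split a structured quad grid into triangles.  `idx` is an n_row x n_col
# matrix of node ids; with rows advancing along +x and columns along +y the
# quads (i,j)-(i+1,j)-(i+1,j+1)-(i,j+1) are counter-clockwise.
grid_triangles <- function(idx) {
  nr <- nrow(idx)
  nc <- ncol(idx)
  i <- rep(seq_len(nr - 1L), nc - 1L)
  j <- rep(seq_len(nc - 1L), each = nr - 1L)
  a <- idx[cbind(i, j)]
  b <- idx[cbind(i, j + 1L)]
  cc <- idx[cbind(i + 1L, j + 1L)]
  d <- idx[cbind(i + 1L, j)]
  rbind(cbind(a, d, cc), cbind(a, cc, b))
}

#' Mesh the parametric proximal femur
#'
#' @param geom A `coxa_geometry` from [build_outline()] /
#'   [carve_lesion()].
#' @param h Target edge length in mm; must satisfy `0 < h < R/2` and
#'   `h <= t / 1.5` so the cortical shell is resolved by at least one element
#'   row.
#' @param seed Accepted for interface stability and recorded, but unused: the
#'   mapped construction is fully deterministic.
#' @return A `coxa_mesh` with node coordinates (mm), counter-clockwise
#'   triangles, and labelled boundary parts (`articular`, `medial_neck`,
#'   `medial_shaft`, `distal_cut`, `lateral_shaft`, `trochanter`).
#' @export
#' @examples
#' mesh <- triangulate(build_outline(geometry_params()), h = 2.5)
#' mesh
triangulate <- function(geom, h = 1.0, seed = NULL) {
  stopifnot(inherits(geom, "coxa_geometry"))
  fr <- geom$frame
  R <- fr$R
  if (!(h > 0 && h < R / 2)) {
    stop("meshing error: target edge length h must satisfy 0 < h < R/2",
         call. = FALSE)
  }
  if (h > fr$t / 1.5 + 1e-12) {
    stop(sprintf(
      "meshing error: h = %g mm is too coarse to resolve the cortical shell (t = %g mm); use h <= t/1.5 = %g mm",
      h, fr$t, fr$t / 1.5
    ), call. = FALSE)
  }

  # --- head: polar grid ------------------------------------------------------
  req_ang <- c(fr$theta_med, fr$theta_lat, fr$a_med + 360)
  les <- geom$lesion
  if (!is.null(les) && les$label != "NORMAL") {
    req_ang <- c(req_ang, les$a1, les$a2)
  }
  lo <- fr$a_lat
  req_ang <- ((req_ang - lo) %% 360) + lo
  spokes <- merge_breaks(lo, lo + 360, (h / R) * 180 / pi, req_ang)
  spokes <- spokes[-length(spokes)]          # drop duplicate wrap angle
  K <- length(spokes)

  req_r <- R - fr$t
  if (!is.null(les) && les$label != "NORMAL") {
    req_r <- c(req_r, les$r_in, les$r_out)
  }
  rings <- merge_breaks(0, R, h, req_r)[-1]  # exclude r = 0 (centre node)
  nr <- length(rings)

  th <- spokes * pi / 180
  nodes <- rbind(
    c(0, 0),
    cbind(rep(rings, each = K) * cos(th), rep(rings, each = K) * sin(th))
  )
  node_id <- function(i, j) 1L + (i - 1L) * K + ((j - 1L) %% K) + 1L

  tris <- vector("list", nr + 1L)
  jj <- seq_len(K)
  jn <- c(seq_len(K)[-1], 1L)
  tris[[1]] <- cbind(1L, node_id(1L, jj), node_id(1L, jn))
  for (i in seq_len(nr - 1L)) {
    # counter-clockwise band quads: inner j, outer j, outer j+1, inner j+1
    a <- node_id(i, jj); b <- node_id(i, jn)
    cc <- node_id(i + 1L, jn); d <- node_id(i + 1L, jj)
    tris[[i + 1L]] <- rbind(cbind(a, d, cc), cbind(a, cc, b))
  }

  # --- stem: transfinite patch under the junction arc ------------------------
  j_lo <- fr$a_med + 360
  j_spokes <- c(spokes[spokes >= j_lo - 1e-9], lo + 360)
  s <- (j_spokes - j_lo) / (j_spokes[length(j_spokes)] - j_lo)
  ns <- length(s)
  top <- cbind(R * cos(j_spokes * pi / 180), R * sin(j_spokes * pi / 180))
  top_ids <- c(node_id(nr, match_angles(spokes, j_spokes[-length(j_spokes)])),
               node_id(nr, 1L))

  polyline_point <- function(pl, tq) {
    seg <- sqrt(rowSums(diff(pl)^2))
    cum <- c(0, cumsum(seg)) / sum(seg)
    x <- stats::approx(cum, pl[, 1], xout = tq)$y
    y <- stats::approx(cum, pl[, 2], xout = tq)$y
    cbind(x, y)
  }
  len_m <- sum(sqrt(rowSums(diff(fr$medial_border)^2)))
  len_l <- sum(sqrt(rowSums(diff(fr$lateral_border)^2)))
  m_t <- max(4L, ceiling(max(len_m, len_l) / h))
  tq <- seq(0, 1, length.out = m_t + 1L)
  left <- polyline_point(fr$medial_border, tq)
  right <- polyline_point(fr$lateral_border, tq)
  M2 <- fr$medial_border[3, ]
  L2 <- fr$lateral_border[3, ]
  bot <- cbind(M2[1] + s * (L2[1] - M2[1]), M2[2] + s * (L2[2] - M2[2]))

  # transfinite interpolation over (s across, t down); t = 0 row is the arc
  S <- matrix(rep(s, each = m_t + 1L), nrow = m_t + 1L)
  Tm <- matrix(rep(tq, ns), nrow = m_t + 1L)
  C00 <- top[1, ]; C10 <- top[ns, ]; C01 <- M2; C11 <- L2
  stem_x <- (1 - Tm) * matrix(rep(top[, 1], each = m_t + 1L), nrow = m_t + 1L) +
    Tm * matrix(rep(bot[, 1], each = m_t + 1L), nrow = m_t + 1L) +
    (1 - S) * matrix(rep(left[, 1], ns), nrow = m_t + 1L) +
    S * matrix(rep(right[, 1], ns), nrow = m_t + 1L) -
    ((1 - S) * (1 - Tm) * C00[1] + S * (1 - Tm) * C10[1] +
       (1 - S) * Tm * C01[1] + S * Tm * C11[1])
  stem_y <- (1 - Tm) * matrix(rep(top[, 2], each = m_t + 1L), nrow = m_t + 1L) +
    Tm * matrix(rep(bot[, 2], each = m_t + 1L), nrow = m_t + 1L) +
    (1 - S) * matrix(rep(left[, 2], ns), nrow = m_t + 1L) +
    S * matrix(rep(right[, 2], ns), nrow = m_t + 1L) -
    ((1 - S) * (1 - Tm) * C00[2] + S * (1 - Tm) * C10[2] +
       (1 - S) * Tm * C01[2] + S * Tm * C11[2])

  # stem node ids: row 1 (t = 0) reuses head nodes on the junction arc
  n_head <- nrow(nodes)
  stem_idx <- matrix(0L, nrow = m_t + 1L, ncol = ns)
  stem_idx[1, ] <- top_ids
  new_rows <- 2:(m_t + 1L)
  stem_nodes <- cbind(as.vector(t(stem_x[new_rows, ])),
                      as.vector(t(stem_y[new_rows, ])))
  stem_idx[new_rows, ] <- n_head +
    matrix(seq_len(length(new_rows) * ns), nrow = length(new_rows), byrow = TRUE)
  nodes <- rbind(nodes, stem_nodes)

  # rows advance in s (medial -> lateral, roughly +x); t advances downwards,
  # so reverse the column order to restore counter-clockwise quads
  stem_tris <- grid_triangles(t(stem_idx)[, rev(seq_len(m_t + 1L)), drop = FALSE])
  tri <- rbind(do.call(rbind, tris), stem_tris)
  colnames(tri) <- NULL

  # --- boundary parts --------------------------------------------------------
  art_j <- which(spokes <= j_lo + 1e-9)      # spokes on the articular span
  art_ids <- node_id(nr, art_j)
  boundary <- list(
    tibble::tibble(n1 = art_ids[-length(art_ids)], n2 = art_ids[-1],
                   part = "articular")
  )
  med_ids <- stem_idx[, 1]
  lat_ids <- stem_idx[, ns]
  med_part <- ifelse(tq[-1] <= 0.35, "medial_neck", "medial_shaft")
  lat_part <- ifelse(tq[-1] <= 0.45, "trochanter", "lateral_shaft")
  boundary <- c(boundary, list(
    tibble::tibble(n1 = med_ids[-length(med_ids)], n2 = med_ids[-1],
                   part = med_part),
    tibble::tibble(n1 = lat_ids[-length(lat_ids)], n2 = lat_ids[-1],
                   part = lat_part),
    tibble::tibble(n1 = stem_idx[m_t + 1L, -ns], n2 = stem_idx[m_t + 1L, -1],
                   part = "distal_cut")
  ))
  boundary <- dplyr::bind_rows(boundary)

  mesh <- new_mesh(nodes, tri, boundary, h, extra = list(
    head_radius = R,
    articular = tibble::tibble(node = art_ids, angle = spokes[art_j]),
    seed = seed
  ))
  if (geom$params$side == "left") mesh <- mirror_mesh(mesh)
  stopifnot(all(mesh_areas(mesh) > 0))
  mesh
}

match_angles <- function(spokes, targets) {
  idx <- vapply(targets, function(a) which.min(abs(spokes - a)), integer(1))
  stopifnot(all(abs(spokes[idx] - targets) < 1e-6))
  idx
}

mirror_mesh <- function(mesh) {
  mesh$nodes[, 1] <- -mesh$nodes[, 1]
  mesh$tri <- mesh$tri[, c(1L, 3L, 2L)]
  if (!is.null(mesh$articular)) {
    mesh$articular$angle <- 180 - mesh$articular$angle
  }
  mesh
}

#' Structured mesh of an axis-aligned rectangle
#'
#' @param width,height Rectangle dimensions with lower-left corner at the
#'   origin.
#' @param h Target edge length.
#' @return A `coxa_mesh` with boundary parts `left`, `right`, `bottom`,
#'   `top`.
#' @export
mesh_rectangle <- function(width = 1, height = 1, h = 0.1) {
  stopifnot(h > 0)
  nx <- max(1L, round(width / h))
  ny <- max(1L, round(height / h))
  xs <- seq(0, width, length.out = nx + 1L)
  ys <- seq(0, height, length.out = ny + 1L)
  nodes <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  idx <- matrix(seq_len((nx + 1L) * (ny + 1L)), nrow = nx + 1L)
  tri <- grid_triangles(idx)
  colnames(tri) <- NULL
  left <- idx[1, ]; right <- idx[nx + 1L, ]
  bottom <- idx[, 1]; top <- idx[, ny + 1L]
  band <- function(ids, part) {
    tibble::tibble(n1 = ids[-length(ids)], n2 = ids[-1], part = part)
  }
  boundary <- dplyr::bind_rows(
    band(left, "left"), band(right, "right"),
    band(bottom, "bottom"), band(top, "top")
  )
  new_mesh(nodes, tri, boundary, h)
}

#' Structured mesh of an annulus
#'
#' Polar grid between radii `r_in` and `r_out`, used as the domain of the
#' pressurised thick-walled-cylinder benchmark.
#'
#' @param r_in,r_out Inner and outer radii, `0 < r_in < r_out`.
#' @param h Target edge length.
#' @return A `coxa_mesh` with boundary parts `inner` and `outer`.
#' @export
mesh_annulus <- function(r_in, r_out, h = 1) {
  stopifnot(r_in > 0, r_out > r_in, h > 0)
  spokes <- merge_breaks(0, 360, (h / r_out) * 180 / pi)
  spokes <- spokes[-length(spokes)]
  K <- length(spokes)
  rings <- merge_breaks(r_in, r_out, h)
  nr <- length(rings)
  th <- spokes * pi / 180
  nodes <- cbind(rep(rings, each = K) * cos(th), rep(rings, each = K) * sin(th))
  node_id <- function(i, j) (i - 1L) * K + ((j - 1L) %% K) + 1L
  jj <- seq_len(K)
  jn <- c(seq_len(K)[-1], 1L)
  tris <- vector("list", nr - 1L)
  for (i in seq_len(nr - 1L)) {
    a <- node_id(i, jj); b <- node_id(i, jn)
    cc <- node_id(i + 1L, jn); d <- node_id(i + 1L, jj)
    tris[[i]] <- rbind(cbind(a, d, cc), cbind(a, cc, b))
  }
  tri <- do.call(rbind, tris)
  colnames(tri) <- NULL
  ring_edges <- function(i, part) {
    ids <- node_id(i, jj)
    tibble::tibble(n1 = ids, n2 = ids[jn], part = part)
  }
  boundary <- dplyr::bind_rows(ring_edges(1L, "inner"), ring_edges(nr, "outer"))
  new_mesh(nodes, tri, boundary, h, extra = list(
    inner = tibble::tibble(node = node_id(1L, jj), angle = spokes),
    outer = tibble::tibble(node = node_id(nr, jj), angle = spokes)
  ))
}

# All boundary rings of a mesh, chained from the edges used by exactly one
# triangle and keeping that triangle's orientation: the outer ring comes out
# counter-clockwise (positive area), interior holes clockwise, so the signed
# ring areas sum to the mesh area.
mesh_boundary_rings <- function(mesh) {
  t <- mesh$tri
  e <- rbind(t[, 1:2], t[, 2:3], t[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  single <- e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  nxt <- integer(max(single))
  nxt[single[, 1]] <- single[, 2]
  todo <- rep(FALSE, max(single))
  todo[single[, 1]] <- TRUE
  rings <- list()
  while (any(todo)) {
    start <- which(todo)[1]
    ring <- integer(0)
    cur <- start
    repeat {
      ring <- c(ring, cur)
      todo[cur] <- FALSE
      cur <- nxt[cur]
      if (cur == start || length(ring) > nrow(single) + 1L) break
    }
    rings <- c(rings, list(mesh$nodes[ring, , drop = FALSE]))
  }
  rings
}

#' Extract the outer boundary polygon of a mesh
#'
#' Boundary edges are the triangle edges used by exactly one element; they are
#' chained into rings and the ring with the largest enclosed area (the outer
#' boundary) is returned.
#'
#' @param mesh A `coxa_mesh`.
#' @return Polygon matrix of boundary node coordinates in order.
#' @export
mesh_boundary_polygon <- function(mesh) {
  rings <- mesh_boundary_rings(mesh)
  areas <- vapply(rings, function(r) abs(poly_area(r)), numeric(1))
  rings[[which.max(areas)]]
}
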