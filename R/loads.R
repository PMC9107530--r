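# Load case: abduction-rotated joint contact pressure, muscle point loads,
# and the distal support set.
#
# The paper-equivalent statement "fix the pelvis, load a plate tied to the
# distal femur" is inverted for a femur-only domain: the distal cut is fully
# constrained and the joint contact pressure plus muscle forces are applied.
# By superposition and Saint-Venant's principle the stress field in the head
# is the same static problem.
#
# Abduction kinematics: abducting the femur by beta rotates the femur
# counter-clockwise relative to the pelvis, so a pelvis-fixed joint-load
# direction rotates by -beta in the femur frame, i.e. the contact centroid
# moves laterally (towards smaller angles) as beta grows.

#' Default muscle force table
#'
#' Seven muscles modelled as point loads at their attachment sites, with the
#' standard single-leg-stance magnitudes: adductor longus 560 N, adductor
#' magnus 600 N, gluteus maximus 550 N, gluteus medius 700 N, gluteus minimus
#' 300 N, piriformis 500 N, tensor fasciae latae 300 N.  Forces are held
#' independent of the abduction angle.  Directions are fixed unit vectors in
#' the femur frame (+x lateral, +y superior) approximating each muscle's line
#' of action towards its pelvic attachment; `frac` locates the attachment
#' along its boundary part by normalised arclength.
#'
#' @return A tibble with columns `muscle`, `force_N`, `part`, `frac`,
#'   `dir_x`, `dir_y`.
#' @export
#' @examples
#' muscle_table()
muscle_table <- function() {
  tbl <- tibble::tribble(
    ~muscle,                ~force_N, ~part,           ~frac, ~dir_x, ~dir_y,
    "adductor_longus",      560,      "medial_shaft",  0.55,  -0.77,  0.64,
    "adductor_magnus",      600,      "medial_shaft",  0.80,  -0.42,  0.91,
    "gluteus_maximus",      550,      "lateral_shaft", 0.60,  -0.64,  0.77,
    "gluteus_medius",       700,      "trochanter",    0.30,  -0.26,  0.97,
    "gluteus_minimus",      300,      "trochanter",    0.55,  -0.34,  0.94,
    "piriformis",           500,      "trochanter",    0.80,  -0.94,  0.34,
    "tensor_fasciae_latae", 300,      "trochanter",    0.10,  -0.17,  0.98
  )
  nrm <- sqrt(tbl$dir_x^2 + tbl$dir_y^2)
  tbl$dir_x <- tbl$dir_x / nrm
  tbl$dir_y <- tbl$dir_y / nrm
  tbl
}

#' Joint contact pressure as consistent nodal tractions
#'
#' The articular surface carries a radially inward cosine pressure profile
#' `p(theta) = p0 cos(pi/2 (theta - theta_c)/halfwidth)` over the contact arc
#' `|theta - theta_c| <= halfwidth`, with contact centroid
#' `theta_c = theta_c0 - beta`.  Edge tractions are lumped to nodes by the
#' trapezoidal rule and `p0` is scaled so the vector resultant has magnitude
#' exactly `J`.
#'
#' @param mesh A `coxa_mesh` with an `articular` boundary part.
#' @param beta Abduction angle in degrees.
#' @param J Joint resultant magnitude in N (per unit out-of-plane thickness).
#' @param theta_c0 Contact centroid at beta = 0, degrees counter-clockwise
#'   from the lateral +x axis.
#' @param halfwidth Contact half-width in degrees.
#' @return A tibble `node`, `fx`, `fy` of nodal forces (N).
#' @export
joint_pressure <- function(mesh, beta = 0, J = 1600, theta_c0 = 74,
                           halfwidth = 30) {
  art <- mesh$articular
  if (is.null(art) || nrow(art) == 0L) {
    stop("load error: mesh has no articular boundary part", call. = FALSE)
  }
  theta_c <- theta_c0 - beta
  lo <- theta_c - halfwidth
  hi <- theta_c + halfwidth
  if (lo < min(art$angle) - 1e-9 || hi > max(art$angle) + 1e-9) {
    stop(sprintf(
      "load error: contact arc [%.1f, %.1f] deg is not covered by the articular surface [%.1f, %.1f] deg",
      lo, hi, min(art$angle), max(art$angle)
    ), call. = FALSE)
  }
  th <- art$angle
  p <- ifelse(abs(th - theta_c) <= halfwidth,
              cos(pi / 2 * (th - theta_c) / halfwidth), 0)
  xy <- mesh$nodes[art$node, , drop = FALSE]
  nseg <- nrow(art) - 1L
  L <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  wt <- numeric(nrow(art))
  wt[1:nseg] <- wt[1:nseg] + L / 2
  wt[2:(nseg + 1L)] <- wt[2:(nseg + 1L)] + L / 2
  rad <- th * pi / 180
  fx <- -wt * p * cos(rad)
  fy <- -wt * p * sin(rad)
  res <- sqrt(sum(fx)^2 + sum(fy)^2)
  if (res <= 0) stop("load error: zero contact resultant", call. = FALSE)
  scale <- J / res
  keep <- p > 0
  tibble::tibble(node = art$node[keep], fx = fx[keep] * scale,
                 fy = fy[keep] * scale)
}

# Ordered node sequence and normalised arclength along one boundary part.
part_nodes <- function(mesh, part) {
  b <- mesh$boundary[mesh$boundary$part == part, , drop = FALSE]
  if (nrow(b) == 0L) return(NULL)
  ids <- c(b$n1[1], b$n2)
  xy <- mesh$nodes[ids, , drop = FALSE]
  seg <- sqrt(rowSums(diff(xy)^2))
  tibble::tibble(node = ids, s = c(0, cumsum(seg)) / sum(seg))
}

#' Muscle point loads
#'
#' Each muscle force is applied at the boundary node of its attachment part
#' nearest the configured arclength position, along its fixed unit direction.
#'
#' @param mesh A `coxa_mesh`.
#' @param table Muscle table as from [muscle_table()].
#' @return A tibble `muscle`, `node`, `fx`, `fy` with one row per muscle.
#' @export
muscle_loads <- function(mesh, table = muscle_table()) {
  if (nrow(table) == 0L) {
    return(tibble::tibble(muscle = character(0), node = integer(0),
                          fx = numeric(0), fy = numeric(0)))
  }
  rows <- purrr::pmap(table, function(muscle, force_N, part, frac, dir_x, dir_y) {
    pn <- part_nodes(mesh, part)
    if (is.null(pn)) {
      stop(sprintf(
        "configuration error: attachment part '%s' for muscle '%s' is missing from the mesh",
        part, muscle
      ), call. = FALSE)
    }
    node <- pn$node[which.min(abs(pn$s - frac))]
    tibble::tibble(muscle = muscle, node = node,
                   fx = force_N * dir_x, fy = force_N * dir_y)
  })
  dplyr::bind_rows(rows)
}

#' Dirichlet support set at the distal cut
#'
#' All displacement components of every node on the distal cut are fixed,
#' which removes the rigid-body modes of the femur-only model.
#'
#' @param mesh A `coxa_mesh` with a `distal_cut` boundary part.
#' @return Integer vector of constrained node ids.
#' @export
supports <- function(mesh) {
  b <- mesh$boundary[mesh$boundary$part == "distal_cut", , drop = FALSE]
  if (nrow(b) == 0L) {
    stop("model error: mesh has no distal_cut boundary part", call. = FALSE)
  }
  sort(unique(c(b$n1, b$n2)))
}

#' Assemble the complete load case
#'
#' @inheritParams joint_pressure
#' @param muscles Muscle table, or a zero-row tibble for joint pressure only.
#' @return An object of class `coxa_loadcase`: global force vector `f`
#'   (length 2 x nodes, interleaved x/y), `fixed_nodes`, `fixed_dofs`, the
#'   nodal traction and muscle tables, and the parameters.
#' @export
#' @examples
#' geom <- build_outline(geometry_params())
#' mesh <- triangulate(geom, h = 2.5)
#' lc <- load_case(mesh, beta = 0)
#' length(lc$fixed_nodes) > 0
load_case <- function(mesh, beta = 0, J = 1600, theta_c0 = 74, halfwidth = 30,
                      muscles = muscle_table()) {
  tr <- joint_pressure(mesh, beta = beta, J = J, theta_c0 = theta_c0,
                       halfwidth = halfwidth)
  ml <- muscle_loads(mesh, muscles)
  n <- nrow(mesh$nodes)
  f <- numeric(2L * n)
  add <- function(f, node, fx, fy) {
    for (k in seq_along(node)) {
      f[2L * node[k] - 1L] <- f[2L * node[k] - 1L] + fx[k]
      f[2L * node[k]] <- f[2L * node[k]] + fy[k]
    }
    f
  }
  f <- add(f, tr$node, tr$fx, tr$fy)
  if (nrow(ml)) f <- add(f, ml$node, ml$fx, ml$fy)
  fixed_nodes <- supports(mesh)
  fixed_dofs <- sort(c(2L * fixed_nodes - 1L, 2L * fixed_nodes))
  structure(list(
    f = f, fixed_nodes = fixed_nodes, fixed_dofs = fixed_dofs,
    tractions = tr, muscles = ml,
    beta = beta, J = J, theta_c0 = theta_c0, halfwidth = halfwidth
  ), class = "coxa_loadcase")
}

#' @export
print.coxa_loadcase <- function(x, ...) {
  cat("<coxa_loadcase> beta =", x$beta, "deg, J =", x$J, "N, theta_c =",
      x$theta_c0 - x$beta, "deg\n")
  cat(" ", nrow(x$tractions), "contact traction nodes,", nrow(x$muscles),
      "muscle loads,", length(x$fixed_nodes), "supported nodes\n")
  invisible(x)
}
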