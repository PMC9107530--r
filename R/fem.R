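# Plane-strain linear-elastic finite elements on 3-node (constant-strain)
# triangles: element stiffness, vectorised sparse assembly, Dirichlet
# elimination, direct sparse solve, and per-element stress recovery.

plane_strain_D <- function(E, nu) {
  d1 <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  d2 <- E * nu / ((1 + nu) * (1 - 2 * nu))
  d3 <- E / (2 * (1 + nu))
  list(d1 = d1, d2 = d2, d3 = d3)
}

#' Element stiffness of a constant-strain triangle
#'
#' Plane strain, unit out-of-plane thickness.
#'
#' @param coords 3 x 2 matrix of node coordinates (mm), counter-clockwise.
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @param thickness Out-of-plane thickness (mm).
#' @return Symmetric 6 x 6 stiffness matrix (dof order x1, y1, x2, y2, x3,
#'   y3).
#' @export
#' @examples
#' K <- element_stiffness(rbind(c(0, 0), c(1, 0), c(0, 1)), E = 1, nu = 0)
#' max(abs(K - t(K)))
element_stiffness <- function(coords, E, nu, thickness = 1) {
  x <- coords[, 1]
  y <- coords[, 2]
  A <- ((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
  if (!(A > 0)) {
    stop("numerical error: degenerate triangle (area <= 0)", call. = FALSE)
  }
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- b
  B[2, c(2, 4, 6)] <- cc
  B[3, c(1, 3, 5)] <- cc
  B[3, c(2, 4, 6)] <- b
  B <- B / (2 * A)
  Dm <- with(plane_strain_D(E, nu),
             matrix(c(d1, d2, 0, d2, d1, 0, 0, 0, d3), 3, 3))
  thickness * A * t(B) %*% Dm %*% B
}

# Per-element CST geometry arrays shared by assembly and stress recovery.
cst_arrays <- function(mesh) {
  nd <- mesh$nodes
  t <- mesh$tri
  x1 <- nd[t[, 1], 1]; y1 <- nd[t[, 1], 2]
  x2 <- nd[t[, 2], 1]; y2 <- nd[t[, 2], 2]
  x3 <- nd[t[, 3], 1]; y3 <- nd[t[, 3], 2]
  A <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  if (any(A <= 0)) {
    stop("numerical error: degenerate triangle(s) ",
         paste(utils::head(which(A <= 0)), collapse = ", "), call. = FALSE)
  }
  list(
    A = A,
    b = cbind(y2 - y3, y3 - y1, y1 - y2),
    cc = cbind(x3 - x2, x1 - x3, x2 - x1),
    dof = cbind(2L * t[, 1] - 1L, 2L * t[, 1], 2L * t[, 2] - 1L, 2L * t[, 2],
                2L * t[, 3] - 1L, 2L * t[, 3])
  )
}

#' Assemble the global stiffness matrix
#'
#' @param mesh A `coxa_mesh`.
#' @param materials Per-element material tibble from [assign_materials()] (or
#'   any tibble with columns `E`, `nu` in element order).
#' @param thickness Out-of-plane thickness (mm).
#' @return Sparse symmetric stiffness matrix (2 nodes x 2 nodes dofs,
#'   interleaved x/y).
#' @export
assemble_stiffness <- function(mesh, materials, thickness = 1) {
  g <- cst_arrays(mesh)
  D <- plane_strain_D(materials$E, materials$nu)
  # unscaled strain-displacement rows (2A * B), as per-element column vectors
  zero <- numeric(length(g$A))
  Bm1 <- list(g$b[, 1], zero, g$b[, 2], zero, g$b[, 3], zero)
  Bm2 <- list(zero, g$cc[, 1], zero, g$cc[, 2], zero, g$cc[, 3])
  Bm3 <- list(g$cc[, 1], g$b[, 1], g$cc[, 2], g$b[, 2], g$cc[, 3], g$b[, 3])
  DB1 <- lapply(1:6, function(i) D$d1 * Bm1[[i]] + D$d2 * Bm2[[i]])
  DB2 <- lapply(1:6, function(i) D$d2 * Bm1[[i]] + D$d1 * Bm2[[i]])
  DB3 <- lapply(1:6, function(i) D$d3 * Bm3[[i]])
  coef <- thickness / (4 * g$A)
  m <- length(g$A)
  ii <- matrix(0L, m, 36L)
  jj <- matrix(0L, m, 36L)
  xx <- matrix(0, m, 36L)
  k <- 0L
  for (i in 1:6) {
    for (j in 1:6) {
      k <- k + 1L
      ii[, k] <- g$dof[, i]
      jj[, k] <- g$dof[, j]
      xx[, k] <- coef * (Bm1[[i]] * DB1[[j]] + Bm2[[i]] * DB2[[j]] +
                           Bm3[[i]] * DB3[[j]])
    }
  }
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = as.vector(xx),
                       dims = c(2L * nrow(mesh$nodes), 2L * nrow(mesh$nodes)))
}

#' Solve the constrained linear-elastic system
#'
#' Eliminates the Dirichlet dofs and solves the reduced symmetric
#' positive-definite system by direct sparse Cholesky factorisation
#' (deterministic).
#'
#' @param mesh A `coxa_mesh`.
#' @param materials Per-element materials (see [assemble_stiffness()]).
#' @param loadcase A `coxa_loadcase` (or list with `f` and `fixed_dofs`).
#' @param K Optional pre-assembled stiffness (reused across load cases on the
#'   same mesh and materials).
#' @return An object of class `coxa_solution`: nodal displacements `u`
#'   (2 x nodes vector and an n x 2 matrix `U`), support `reactions`,
#'   relative residual, external work and strain energy.
#' @export
#' @examples
#' geom <- build_outline(geometry_params())
#' mesh <- triangulate(geom, h = 2.5)
#' mats <- assign_materials(mesh, geom)
#' sol <- assemble_solve(mesh, mats, load_case(mesh, beta = 0))
#' sol$residual < 1e-8
assemble_solve <- function(mesh, materials, loadcase, K = NULL) {
  if (length(loadcase$fixed_dofs) < 3L) {
    stop("solver error: at least 3 constrained components are required to ",
         "eliminate rigid-body modes", call. = FALSE)
  }
  if (is.null(K)) K <- assemble_stiffness(mesh, materials)
  ndof <- nrow(K)
  free <- setdiff(seq_len(ndof), loadcase$fixed_dofs)
  f <- loadcase$f
  u <- numeric(ndof)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  uf <- tryCatch(
    as.numeric(Matrix::solve(Kff, f[free])),
    error = function(e) {
      stop("solver error: singular or indefinite system (insufficient ",
           "constraints?): ", conditionMessage(e), call. = FALSE)
    }
  )
  u[free] <- uf
  Ku <- as.numeric(K %*% u)
  fn <- sqrt(sum(f[free]^2))
  residual <- if (fn > 0) sqrt(sum((Ku[free] - f[free])^2)) / fn else 0
  reactions <- Ku[loadcase$fixed_dofs] - f[loadcase$fixed_dofs]
  structure(list(
    u = u,
    U = matrix(u, ncol = 2, byrow = TRUE),
    residual = residual,
    reactions = tibble::tibble(
      dof = loadcase$fixed_dofs,
      node = (loadcase$fixed_dofs + 1L) %/% 2L,
      r = reactions
    ),
    external_work = sum(f * u) / 2,
    strain_energy = sum(u * Ku) / 2,
    K = K
  ), class = "coxa_solution")
}

#' @export
print.coxa_solution <- function(x, ...) {
  cat("<coxa_solution>", nrow(x$U), "nodes, residual", format(x$residual),
      "\n  strain energy", format(x$strain_energy), "N mm\n")
  invisible(x)
}

#' Recover per-element stresses
#'
#' Constant stress per element, `sigma = D B u_e`, plane strain with
#' `sigma_zz = nu (sigma_xx + sigma_yy)`.
#'
#' @param mesh A `coxa_mesh`.
#' @param materials Per-element materials.
#' @param sol A `coxa_solution` (or a raw displacement vector of length
#'   2 x nodes).
#' @return A tibble with one row per element: stress components `sxx`, `syy`,
#'   `sxy`, `szz` (MPa), centroid `cx`, `cy`, `area`, and `tissue` when
#'   available.
#' @export
element_stress <- function(mesh, materials, sol) {
  u <- if (inherits(sol, "coxa_solution")) sol$u else as.numeric(sol)
  g <- cst_arrays(mesh)
  ux <- matrix(u[g$dof[, c(1, 3, 5)]], ncol = 3)
  uy <- matrix(u[g$dof[, c(2, 4, 6)]], ncol = 3)
  inv2A <- 1 / (2 * g$A)
  exx <- rowSums(g$b * ux) * inv2A
  eyy <- rowSums(g$cc * uy) * inv2A
  gxy <- (rowSums(g$cc * ux) + rowSums(g$b * uy)) * inv2A
  D <- plane_strain_D(materials$E, materials$nu)
  sxx <- D$d1 * exx + D$d2 * eyy
  syy <- D$d2 * exx + D$d1 * eyy
  sxy <- D$d3 * gxy
  cen <- mesh_centroids(mesh)
  tibble::tibble(
    element = seq_along(g$A),
    sxx = sxx, syy = syy, sxy = sxy,
    szz = materials$nu * (sxx + syy),
    cx = cen[, 1], cy = cen[, 2], area = g$A,
    tissue = if ("tissue" %in% names(materials)) materials$tissue else NA_character_
  )
}
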