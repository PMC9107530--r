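test_that("element stiffness is symmetric with a rigid-body null space", {
  set.seed(42)
  for (i in 1:20) {
    coords <- matrix(runif(6, -5, 5), 3, 2)
    # enforce counter-clockwise orientation
    a <- (coords[2, 1] - coords[1, 1]) * (coords[3, 2] - coords[1, 2]) -
      (coords[3, 1] - coords[1, 1]) * (coords[2, 2] - coords[1, 2])
    if (a < 0) coords <- coords[c(1, 3, 2), ]
    if (abs(a) < 1e-3) next
    K <- element_stiffness(coords, E = 1200, nu = 0.3)
    expect_lt(max(abs(K - t(K))), 1e-9 * max(abs(K)))
    tx <- rep(c(1, 0), 3)
    ty <- rep(c(0, 1), 3)
    rot <- as.vector(t(cbind(-coords[, 2], coords[, 1])))
    expect_lt(max(abs(K %*% tx)), 1e-10 * max(abs(K)))
    expect_lt(max(abs(K %*% ty)), 1e-10 * max(abs(K)))
    expect_lt(max(abs(K %*% rot)), 1e-9 * max(abs(K)) * max(abs(coords)))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev > 1e-8 * max(ev)), 3L)
  }
})

test_that("unit right triangle matches the hand-assembled B'DB", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1))
  K <- element_stiffness(coords, E = 1, nu = 0)
  # independent hand computation: A = 1/2, B from nodal shape gradients
  b <- c(0 - 1, 1 - 0, 0 - 0)   # y2 - y3, y3 - y1, y1 - y2
  cc <- c(0 - 1, 0 - 0, 1 - 0)  # x3 - x2, x1 - x3, x2 - x1
  A <- 0.5
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- b / (2 * A)
  B[2, c(2, 4, 6)] <- cc / (2 * A)
  B[3, c(1, 3, 5)] <- cc / (2 * A)
  B[3, c(2, 4, 6)] <- b / (2 * A)
  D <- diag(c(1, 1, 0.5))       # plane strain, E = 1, nu = 0
  expect_equal(as.matrix(K), A * t(B) %*% D %*% B, tolerance = 1e-14)
})

test_that("degenerate triangles are rejected", {
  expect_error(element_stiffness(rbind(c(0, 0), c(1, 1), c(2, 2)), 1, 0.3),
               "degenerate")
})

test_that("the uniaxial patch test is exact", {
  pc <- patch_case(s0 = 3.7, nu = 0.25)
  expect_lt(max(abs(pc$stress$sxx - 3.7)), 1e-9)
  expect_lt(max(abs(pc$stress$syy)), 1e-9)
  expect_lt(max(abs(pc$stress$sxy)), 1e-9)
  # plane strain: szz = nu (sxx + syy)
  expect_lt(max(abs(pc$stress$szz - 0.25 * 3.7)), 1e-9)
})

test_that("solutions are linear in the load and reject singular systems", {
  qm <- quick_mesh("NORMAL")
  mats <- assign_materials(qm$mesh, qm$geom)
  lc <- load_case(qm$mesh, beta = 10)
  sol1 <- assemble_solve(qm$mesh, mats, lc)
  expect_lt(sol1$residual, 1e-8)
  lc3 <- lc
  lc3$f <- 3 * lc$f
  sol3 <- assemble_solve(qm$mesh, mats, lc3, K = sol1$K)
  expect_equal(sol3$u, 3 * sol1$u, tolerance = 1e-12)

  few <- lc
  few$fixed_dofs <- lc$fixed_dofs[1:2]
  expect_error(assemble_solve(qm$mesh, mats, few),
               "at least 3 constrained components")
})

test_that("rigid-body displacement fields produce zero stress", {
  qm <- quick_mesh("NORMAL")
  mats <- assign_materials(qm$mesh, qm$geom)
  nd <- qm$mesh$nodes
  phi <- 1e-3
  u <- as.vector(t(cbind(0.5 - phi * nd[, 2], -0.2 + phi * nd[, 1])))
  st <- element_stress(qm$mesh, mats, u)
  scale <- max(mats$E) * phi
  expect_lt(max(abs(c(st$sxx, st$syy, st$sxy))), 1e-9 * scale)
})

test_that("the pressurised annulus matches the closed-form solution", {
  lame1 <- cached("lame_h1", lame_case(h = 1))
  expect_lt(lame1$ur_err, 0.02)
  expect_lt(lame1$hoop_err, 0.03)
  expect_lt(lame1$energy_err, 1e-8)

  # errors decrease monotonically under refinement
  errs <- c(lame_case(h = 2)$ur_err, lame1$ur_err, lame_case(h = 0.5)$ur_err)
  expect_true(all(diff(errs) < 0))
})

test_that("external work equals strain energy on the femur model", {
  qm <- quick_mesh("B")
  mats <- assign_materials(qm$mesh, qm$geom)
  sol <- assemble_solve(qm$mesh, mats, load_case(qm$mesh, beta = 15))
  expect_lt(abs(sol$external_work - sol$strain_energy) /
              abs(sol$external_work), 1e-8)
})
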