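mesh_for_loads <- function() cached("loads_mesh", quick_mesh("NORMAL")$mesh)

test_that("contact tractions resolve to the joint resultant at any abduction", {
  mesh <- mesh_for_loads()
  for (beta in c(0, 10, 25, 30)) {
    tr <- joint_pressure(mesh, beta = beta, J = 1600)
    res <- c(sum(tr$fx), sum(tr$fy))
    expect_lt(abs(sqrt(sum(res^2)) - 1600) / 1600, 0.005)
    # resultant points radially inward through the contact centroid
    theta_c <- (74 - beta) * pi / 180
    axis <- -c(cos(theta_c), sin(theta_c))
    cosang <- sum(res * axis) / sqrt(sum(res^2))
    expect_gt(cosang, 0.9999)
  }
})

test_that("tractions are linear in J and equivariant under load-axis rotation", {
  mesh <- mesh_for_loads()
  t1 <- joint_pressure(mesh, beta = 10, J = 800)
  t2 <- joint_pressure(mesh, beta = 10, J = 1600)
  expect_identical(t1$node, t2$node)
  expect_equal(2 * t1$fx, t2$fx, tolerance = 1e-12)
  expect_equal(2 * t1$fy, t2$fy, tolerance = 1e-12)

  # rotating the axis by beta and rotating the reference back are identical
  a <- joint_pressure(mesh, beta = 12, theta_c0 = 74)
  b <- joint_pressure(mesh, beta = 0, theta_c0 = 74 - 12)
  expect_identical(a, b)
})

test_that("contact arcs outside the articular surface are rejected", {
  mesh <- mesh_for_loads()
  expect_error(joint_pressure(mesh, beta = 200), "not covered")
  bad <- mesh
  bad$articular <- NULL
  expect_error(joint_pressure(bad), "no articular boundary")
})

test_that("the default muscle set applies seven loads with the standard magnitudes", {
  mesh <- mesh_for_loads()
  ml <- muscle_loads(mesh)
  expect_equal(nrow(ml), 7L)
  expect_equal(length(unique(ml$node)), 7L)
  mags <- sqrt(ml$fx^2 + ml$fy^2)
  expect_equal(sort(mags), sort(c(560, 600, 550, 700, 300, 500, 300)),
               tolerance = 1e-9)
  gm <- ml[ml$muscle == "gluteus_medius", ]
  expect_equal(sqrt(gm$fx^2 + gm$fy^2), 700, tolerance = 1e-9)
})

test_that("an empty muscle table leaves the joint pressure as the only load", {
  mesh <- mesh_for_loads()
  empty <- muscle_table()[0, ]
  lc <- load_case(mesh, muscles = empty)
  expect_equal(nrow(lc$muscles), 0L)
  tr <- joint_pressure(mesh)
  expect_equal(sum(abs(lc$f)), sum(abs(c(tr$fx, tr$fy))))
})

test_that("a missing attachment part names the muscle", {
  mesh <- mesh_for_loads()
  tbl <- muscle_table()
  tbl$part[tbl$muscle == "piriformis"] <- "acetabulum"
  expect_error(muscle_loads(mesh, tbl), "piriformis")
})

test_that("supports fix the whole distal cut and carry the reactions", {
  qm <- quick_mesh("NORMAL")
  mesh <- qm$mesh
  sup <- supports(mesh)
  distal <- mesh$boundary[mesh$boundary$part == "distal_cut", ]
  expect_setequal(sup, unique(c(distal$n1, distal$n2)))

  mats <- assign_materials(mesh, qm$geom)
  lc <- load_case(mesh, beta = 0)
  expect_setequal(lc$fixed_dofs, c(2L * sup - 1L, 2L * sup))
  sol <- assemble_solve(mesh, mats, lc)
  # global equilibrium: reactions balance applied loads
  fx <- sum(lc$f[seq(1, length(lc$f), 2)])
  fy <- sum(lc$f[seq(2, length(lc$f), 2)])
  rx <- sum(sol$reactions$r[sol$reactions$dof %% 2 == 1])
  ry <- sum(sol$reactions$r[sol$reactions$dof %% 2 == 0])
  fmag <- sqrt(fx^2 + fy^2)
  expect_lt(abs(fx + rx) / fmag, 1e-6)
  expect_lt(abs(fy + ry) / fmag, 1e-6)
})

test_that("zero loads give zero displacement", {
  qm <- quick_mesh("NORMAL")
  mats <- assign_materials(qm$mesh, qm$geom)
  lc <- load_case(qm$mesh)
  lc$f[] <- 0
  sol <- assemble_solve(qm$mesh, mats, lc)
  expect_equal(max(abs(sol$u)), 0)
})
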