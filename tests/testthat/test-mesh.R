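test_that("unit-square mesh conserves area exactly", {
  mesh <- mesh_rectangle(1, 1, 0.5)
  a <- mesh_areas(mesh)
  expect_true(all(a > 0))
  expect_lt(abs(sum(a) - 1), 1e-9)
  expect_setequal(unique(mesh$boundary$part), c("left", "right", "bottom", "top"))
})

test_that("femur mesh is deterministic and conserves area", {
  qm <- quick_mesh("B")
  m2 <- triangulate(qm$geom, h = 2)
  expect_identical(qm$mesh$nodes, m2$nodes)
  expect_identical(qm$mesh$tri, m2$tri)

  a <- mesh_areas(qm$mesh)
  expect_true(all(a > 0))
  bp <- mesh_boundary_polygon(qm$mesh)
  expect_lt(abs(sum(a) - poly_area(bp)) / sum(a), 1e-9)
  # and the mesh tracks the geometry outline to arc-chord accuracy
  expect_lt(abs(sum(a) - poly_area(qm$geom$outline)) / sum(a), 5e-3)
})

test_that("halving the edge length multiplies the element count by 3 to 5", {
  geom <- build_outline(quick_params())
  n1 <- nrow(triangulate(geom, h = 2)$tri)
  n2 <- nrow(triangulate(geom, h = 1)$tri)
  expect_gt(n2 / n1, 3)
  expect_lt(n2 / n1, 5)
})

test_that("necrotic tagging stays inside the lesion polygon", {
  qm <- quick_mesh("C1")
  mats <- assign_materials(qm$mesh, qm$geom)
  cen <- mesh_centroids(qm$mesh)
  nec <- mats$tissue == "necrotic"
  expect_gt(sum(nec), 0)
  wedge <- qm$geom$regions$necrotic[[1]]
  # oracle: independent point-in-polygon test against the wedge polygon
  inside <- pracma::inpolygon(cen[nec, 1], cen[nec, 2],
                              wedge[, 1], wedge[, 2], boundary = TRUE)
  expect_true(all(inside))
})

test_that("boundary edges belong to exactly one triangle and parts cover them", {
  mesh <- quick_mesh("NORMAL")$mesh
  t <- mesh$tri
  e <- rbind(t[, 1:2], t[, 2:3], t[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  single <- names(which(table(key) == 1L))
  labelled <- paste(pmin(mesh$boundary$n1, mesh$boundary$n2),
                    pmax(mesh$boundary$n1, mesh$boundary$n2))
  expect_setequal(single, labelled)
  expect_true(all(c("articular", "distal_cut", "trochanter") %in%
                    mesh$boundary$part))
})

test_that("tissue area fractions are stable under refinement", {
  geom <- carve_lesion(build_outline(quick_params()), jic_type("B"))
  frac <- function(h) {
    mesh <- triangulate(geom, h = h)
    mats <- assign_materials(mesh, geom)
    tapply(mats$area, mats$tissue, sum) / sum(mats$area)
  }
  f1 <- frac(2)
  f2 <- frac(1)
  expect_true(all(abs(f1 - f2[names(f1)]) < 0.02))
})

test_that("meshing errors report their cause", {
  geom <- build_outline(geometry_params())   # t = 1.5 mm
  expect_error(triangulate(geom, h = 20), "h < R/2")
  expect_error(triangulate(geom, h = 1.4), "h <= t/1.5")
})

test_that("annulus mesh conserves area and exposes its rings", {
  mesh <- mesh_annulus(12.5, 25, 1)
  rings <- coxafem:::mesh_boundary_rings(mesh)
  expect_length(rings, 2L)
  # signed ring areas (outer CCW, hole CW) sum to the triangulated area
  ring_area <- sum(vapply(rings, poly_area, numeric(1)))
  expect_lt(abs(sum(mesh_areas(mesh)) - ring_area) / sum(mesh_areas(mesh)),
            1e-9)
  expect_setequal(unique(mesh$boundary$part), c("inner", "outer"))
  r_in <- sqrt(rowSums(mesh$nodes[mesh$inner$node, ]^2))
  expect_equal(max(abs(r_in - 12.5)), 0)
})
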