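test_that("outline construction is deterministic and validates parameters", {
  p <- geometry_params()
  g1 <- build_outline(p)
  g2 <- build_outline(p)
  expect_identical(g1$outline, g2$outline)
  expect_identical(g1$regions, g2$regions)

  expect_error(geometry_params(head_radius = -1), "R > 0")
  expect_error(geometry_params(cortical_thickness = 0.3), "0 < t < 0.2")
  expect_error(geometry_params(weight_bearing_arc = c(45, 135)),
               "theta_med > theta_lat")
  expect_error(geometry_params(lesion_depth_fraction = 1.2), "0 < d < 1")
})

test_that("cortical shell area vanishes as thickness goes to zero", {
  tfs <- c(0.08, 0.02, 0.005, 1e-4)
  areas <- vapply(tfs, function(tf) {
    g <- build_outline(geometry_params(cortical_thickness = tf))
    sum(vapply(g$regions$cortical, function(p) abs(poly_area(p)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
  expect_lt(areas[length(areas)], 1)   # mm^2, essentially gone
  # shell area scales linearly with thickness (perimeter x t)
  expect_equal(areas[1] / areas[4], tfs[1] / tfs[4], tolerance = 0.05)
})

test_that("outline area matches an independent membership estimate within 1%", {
  g <- build_outline(geometry_params())
  # independent oracle: dense point grid classified by point-in-polygon
  step <- 0.4
  xs <- seq(-30, 48, by = step)
  ys <- seq(-75, 30, by = step)
  pts <- expand.grid(x = xs, y = ys)
  inside <- pracma::inpolygon(pts$x, pts$y, g$outline[, 1], g$outline[, 2])
  est <- sum(inside) * step^2
  expect_lt(abs(est - poly_area(g$outline)) / est, 0.01)
  # the union contains the full head disk: the stem attaches outside the
  # circle, so outline area = disk + stem with no overlap to subtract
  expect_gt(poly_area(g$outline), pi * 25^2)
})

test_that("JIC wedge spans follow the arc fractions", {
  g <- build_outline(geometry_params())   # 90 degree weight-bearing arc
  lesA <- carve_lesion(g, jic_type("A"))
  # medial one-third of a 90 degree arc is a 30 degree wedge
  expect_equal(lesA$lesion$a2 - lesA$lesion$a1, 30)
  expect_equal(lesA$lesion$a2, 135)

  lesC2 <- carve_lesion(g, jic_type("C2"))
  # full arc plus the configured 10 degree lateral overhang
  expect_equal(lesC2$lesion$a1, 45 - 10)
})

test_that("wedge areas follow the annular-sector formula and JIC ordering", {
  g <- build_outline(geometry_params())
  wedge_area <- function(label) {
    les <- carve_lesion(g, jic_type(label))
    poly <- les$regions$necrotic[[1]]
    analytic <- les$lesion$area
    expect_lt(abs(abs(poly_area(poly)) - analytic) / analytic, 5e-3)
    analytic
  }
  areas <- vapply(c("A", "B", "C1", "C2"), wedge_area, numeric(1))
  # equal depth: area proportional to angular width, so B is twice A
  expect_lt(abs(areas[["B"]] / areas[["A"]] - 2), 1e-9)
  # strictly increasing severity NORMAL < A < B < C1 < C2
  expect_true(all(diff(c(0, areas)) > 0))
})

test_that("carving contracts are enforced", {
  g <- build_outline(geometry_params())
  norm <- carve_lesion(g, jic_type("NORMAL"))
  expect_length(norm$regions$necrotic, 0)
  expect_identical(norm$regions$cortical, g$regions$cortical)
  expect_identical(norm$regions$trabecular, g$regions$trabecular)

  les <- carve_lesion(g, jic_type("B"))
  expect_error(carve_lesion(les, jic_type("A")), "already carries a lesion")
  expect_error(
    carve_lesion(g, list(label = "NORMAL", arc_fraction = 0.2)),
    "contract violation"
  )
  expect_error(jic_type("A", arc_fraction = 0.5), "inconsistent")
  expect_error(jic_type("C2", reaches_lateral_edge = FALSE), "inconsistent")
})

test_that("left-side geometry is the exact mirror image", {
  pR <- geometry_params(side = "right")
  pL <- geometry_params(side = "left")
  gR <- build_outline(pR)
  gL <- build_outline(pL)
  mir <- gR$outline
  mir[, 1] <- -mir[, 1]
  expect_equal(sort(gL$outline[, 1]), sort(mir[, 1]))
  expect_equal(poly_area(gL$outline), poly_area(gR$outline), tolerance = 1e-12)

  lesR <- carve_lesion(gR, jic_type("B"))
  lesL <- carve_lesion(gL, jic_type("B"))
  pts <- cbind(c(5, -5, 10, 0), c(20, 20, 18, 24))
  expect_identical(region_label(lesR, pts[, 1], pts[, 2]),
                   region_label(lesL, -pts[, 1], pts[, 2]))
})

test_that("every point of the domain belongs to exactly one tissue region", {
  les <- carve_lesion(build_outline(geometry_params()), jic_type("C1"))
  mesh <- triangulate(les, h = 1)
  cen <- mesh_centroids(mesh)
  lab <- region_label(les, cen[, 1], cen[, 2])
  expect_false(anyNA(lab))
  expect_setequal(unique(lab), c("cortical", "trabecular", "necrotic"))
  # region areas partition the domain
  by_lab <- tapply(mesh_areas(mesh), lab, sum)
  expect_equal(sum(by_lab), sum(mesh_areas(mesh)))
})

test_that("S1/S2 masks are disjoint, nested in their tissues, and shrink with width", {
  geom <- build_outline(geometry_params())
  masks <- region_masks(geom)
  mesh <- triangulate(geom, h = 1)
  cen <- mesh_centroids(mesh)
  lab <- region_label(geom, cen[, 1], cen[, 2])
  in1 <- points_in_poly(cen[, 1], cen[, 2], masks$S1)
  in2 <- points_in_poly(cen[, 1], cen[, 2], masks$S2)
  expect_false(any(in1 & in2))
  expect_true(all(lab[in1] == "cortical"))
  expect_true(all(lab[in2] == "trabecular"))

  ws <- c(0.3, 0.1, 0.02, 2e-4)
  areas <- vapply(ws, function(w) {
    abs(poly_area(region_masks(geom, region_spec(corridor_halfwidth = w))$S2))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
  expect_lt(areas[length(areas)], 1)   # mm^2: corridor collapses with w
})

test_that("the S2 corridor contains the head-centre-to-calcar segment", {
  geom <- build_outline(geometry_params())
  S2 <- region_masks(geom)$S2
  calcar <- geom$frame$A_med
  for (t in seq(0.05, 0.85, by = 0.1)) {
    p <- t * calcar
    expect_true(points_in_poly(p[1], p[2], S2), label = paste("t =", t))
  }
})
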