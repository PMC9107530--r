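fake_stress <- function(sxx, syy, sxy, nu = 0.3) {
  tibble::tibble(sxx = sxx, syy = syy, sxy = sxy, szz = nu * (sxx + syy),
                 cx = 0, cy = 0, area = 1, tissue = NA_character_)
}

test_that("principal decomposition handles the closed-form cases", {
  hyd <- principal_decompose(fake_stress(-5, -5, 0))
  expect_equal(hyd$s1, -5)
  expect_equal(hyd$s2, -5)
  expect_equal(hyd$pcs, 5)

  sh <- principal_decompose(fake_stress(0, 0, 2.5))
  expect_equal(sh$s1, 2.5)
  expect_equal(sh$s2, -2.5)
  expect_equal(sh$pcs, 2.5)

  tens <- principal_decompose(fake_stress(3, 1, 0))
  expect_equal(tens$pcs, 0)   # no compression anywhere
})

test_that("principal values match a generic eigensolver on random tensors", {
  set.seed(7)
  for (i in 1:200) {
    s <- runif(3, -10, 10)
    pd <- principal_decompose(fake_stress(s[1], s[2], s[3]))
    ev <- eigen(matrix(c(s[1], s[3], s[3], s[2]), 2, 2), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lt(abs(pd$s1 - ev[1]), 1e-10)
    expect_lt(abs(pd$s2 - ev[2]), 1e-10)
    # tensor trace is preserved
    expect_lt(abs((pd$s1 + pd$s2) - (s[1] + s[2])), 1e-9)
  }
})

test_that("principal values are invariant under in-plane rotation", {
  set.seed(11)
  for (i in 1:50) {
    s <- runif(3, -10, 10)
    a <- runif(1, 0, 2 * pi)
    cs <- cos(a); sn <- sin(a)
    Q <- matrix(c(cs, sn, -sn, cs), 2, 2)
    S <- matrix(c(s[1], s[3], s[3], s[2]), 2, 2)
    Sr <- Q %*% S %*% t(Q)
    p0 <- principal_decompose(fake_stress(s[1], s[2], s[3]))
    pr <- principal_decompose(fake_stress(Sr[1, 1], Sr[2, 2], Sr[1, 2]))
    expect_lt(abs(p0$s1 - pr$s1), 1e-9)
    expect_lt(abs(p0$s2 - pr$s2), 1e-9)
  }
})

test_that("percent change follows the definition and guards its domain", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(2, 1), 100)
  expect_equal(percent_change(1.5, 1.0), 50)
  expect_equal(percent_change(1.0, 1.5), -100 / 3)
  expect_error(percent_change(1, 0), "domain error")
})

test_that("LSR is one for a homogeneous field and invariant to load scale", {
  # synthetic uniform-stress patch covering both masks
  xs <- seq(-0.9, 0.9, by = 0.2)
  grid <- expand.grid(cx = xs, cy = xs)
  st <- tibble::tibble(sxx = -4, syy = -4, sxy = 0, szz = -2.4,
                       cx = grid$cx, cy = grid$cy, area = 0.04,
                       tissue = NA_character_)
  masks <- list(
    S1 = cbind(c(-1, 0, 0, -1), c(-1, -1, 1, 1)),
    S2 = cbind(c(0.01, 1, 1, 0.01), c(-1, -1, 1, 1))
  )
  l <- lsr(st, masks)
  expect_equal(l$LSR, 1)
  expect_equal(l$S1_avg_MPa, 4)

  sc <- st
  sc$sxx <- 7 * sc$sxx; sc$syy <- 7 * sc$syy; sc$sxy <- 7 * sc$sxy
  expect_equal(lsr(sc, masks)$LSR, l$LSR)
  expect_equal(lsr(sc, masks)$S1_avg_MPa, 7 * l$S1_avg_MPa)

  off <- list(S1 = masks$S1 + 100, S2 = masks$S2)
  expect_error(lsr(st, off), "empty intersection")
})

test_that("LSR and active area are invariant to global load scaling end to end", {
  qm <- quick_mesh("B")
  mats <- assign_materials(qm$mesh, qm$geom)
  masks <- region_masks(qm$geom)
  run <- function(J) {
    sol <- assemble_solve(qm$mesh, mats, load_case(qm$mesh, J = J,
                                                   muscles = muscle_table()[0, ]))
    principal_decompose(element_stress(qm$mesh, mats, sol))
  }
  s1 <- run(1600)
  s2 <- run(3200)
  expect_equal(lsr(s1, masks)$LSR, lsr(s2, masks)$LSR, tolerance = 1e-9)
  r1 <- pcs_reference(s1, 25)
  r2 <- pcs_reference(s2, 25)
  expect_equal(active_area(s1, 25, r1), active_area(s2, 25, r2),
               tolerance = 1e-12)
})

test_that("active area hits its limiting values and requires a reference", {
  xs <- seq(-20, 20, by = 2)
  grid <- expand.grid(cx = xs, cy = xs)
  st <- tibble::tibble(sxx = -10, syy = -2, sxy = 0, szz = -3.6,
                       cx = grid$cx, cy = grid$cy, area = 4,
                       tissue = NA_character_)
  expect_equal(active_area(st, 25, reference_pcs = 50, tau_frac = 0), 1)
  expect_equal(active_area(st, 25, reference_pcs = 50, tau_frac = 10), 0)
  expect_error(active_area(st, 25, reference_pcs = NA), "sequencing error")
})

test_that("the pattern classifier self-matches, clamps, and breaks ties healthier", {
  ref <- tibble::tibble(
    condition = c("NORMAL", "A", "B", "C1", "C2"),
    active_area_fraction = c(0.8, 0.7, 0.6, 0.5, 0.4)
  )
  expect_equal(classify_pattern(0.7, ref), "A")
  expect_equal(classify_pattern(0.95, ref), "NORMAL")  # above the normal ref
  expect_equal(classify_pattern(0.05, ref), "C2")
  expect_equal(classify_pattern(0.75, ref), "NORMAL")  # tie -> healthier
  expect_equal(classify_pattern(0.55, ref), "B")
  expect_error(classify_pattern(0.5, ref[0, ]), "sequencing error")
})

test_that("the von Mises measure includes the out-of-plane component", {
  st <- fake_stress(-10, -10, 0, nu = 0.3)   # szz = -6
  vm <- stress_measure(st, "vonmises")
  expect_equal(vm, sqrt(0.5 * (0 + 16 + 16)), tolerance = 1e-12)
  expect_equal(stress_measure(st, "pcs"), 10)
})
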