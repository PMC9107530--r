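# Shared fixtures.  Everything is generated in code; heavy grid results are
# computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Geometry with a thicker shell so unit tests can use a coarse (fast) mesh:
# h <= t/1.5 allows h = 2 mm at t = 3 mm.
quick_params <- function(...) {
  geometry_params(cortical_thickness = 0.12, ...)
}

quick_mesh <- function(cond = "NORMAL", h = 2, ...) {
  geom <- carve_lesion(build_outline(quick_params(...)), jic_type(cond))
  list(geom = geom, mesh = triangulate(geom, h = h))
}

default_grid <- function() {
  cached("grid_h1", run_grid(grid_spec()))
}

refined_grid <- function() {
  cached("grid_h05", run_grid(grid_spec(h = 0.5)))
}

vonmises_grid <- function() {
  cached("grid_vm", run_grid(grid_spec(measure = "vonmises")))
}

# Pressurised thick-walled annulus (plane strain) solved numerically, with
# the closed-form elasticity solution for comparison.
lame_case <- function(h, a = 12.5, b = 25, p = 1, E = 1000, nu = 0.3) {
  mesh <- mesh_annulus(a, b, h)
  nd <- mesh$nodes
  n <- nrow(nd)
  inner <- mesh$inner
  th <- inner$angle * pi / 180
  xy <- nd[inner$node, , drop = FALSE]
  K <- nrow(inner)
  nxt <- c(2:K, 1L)
  L <- sqrt(rowSums((xy[nxt, , drop = FALSE] - xy)^2))
  wt <- (L + L[c(K, 1:(K - 1))]) / 2
  f <- numeric(2 * n)
  f[2 * inner$node - 1] <- p * wt * cos(th)
  f[2 * inner$node] <- p * wt * sin(th)
  # symmetry constraints compatible with the axisymmetric solution
  ang <- atan2(nd[, 2], nd[, 1]) * 180 / pi
  near <- function(a0) which(abs(((ang - a0 + 180) %% 360) - 180) < 1e-6)
  fixed <- sort(unique(c(2 * near(0), 2 * near(180),
                         2 * near(90) - 1, 2 * near(270) - 1)))
  mats <- tibble::tibble(E = rep(E, nrow(mesh$tri)), nu = nu)
  sol <- assemble_solve(mesh, mats, list(f = f, fixed_dofs = fixed))
  st <- element_stress(mesh, mats, sol)

  r <- sqrt(rowSums(nd^2))
  outn <- mesh$outer$node
  ur_out <- mean(rowSums(sol$U[outn, , drop = FALSE] *
                           nd[outn, , drop = FALSE] / r[outn]))
  ur_exact <- 2 * p * a^2 * b * (1 - nu^2) / (E * (b^2 - a^2))

  rc <- sqrt(st$cx^2 + st$cy^2)
  sel <- rc < a + 0.8 * h
  thc <- atan2(st$cy, st$cx)
  hoop <- st$sxx * sin(thc)^2 + st$syy * cos(thc)^2 -
    2 * st$sxy * sin(thc) * cos(thc)
  rmid <- mean(rc[sel])
  hoop_num <- mean(hoop[sel])
  hoop_exact <- p * a^2 / (b^2 - a^2) * (1 + b^2 / rmid^2)

  list(
    sol = sol,
    ur_err = abs(ur_out - ur_exact) / ur_exact,
    hoop_err = abs(hoop_num - hoop_exact) / abs(hoop_exact),
    energy_err = abs(sol$external_work - sol$strain_energy) /
      abs(sol$external_work)
  )
}

# Uniaxial patch test on the unit square: traction s0 on the right edge,
# rollers on the left edge, one corner pinned vertically.
patch_case <- function(s0 = 3.7, nu = 0.25, h = 0.5) {
  mesh <- mesh_rectangle(1, 1, h)
  nd <- mesh$nodes
  n <- nrow(nd)
  right <- which(abs(nd[, 1] - 1) < 1e-12)
  right <- right[order(nd[right, 2])]
  seg <- diff(nd[right, 2])
  wt <- c(seg / 2, 0) + c(0, seg / 2)
  f <- numeric(2 * n)
  f[2 * right - 1] <- s0 * wt
  left <- which(abs(nd[, 1]) < 1e-12)
  corner <- which(abs(nd[, 1]) < 1e-12 & abs(nd[, 2]) < 1e-12)
  fixed <- sort(unique(c(2 * left - 1, 2 * corner)))
  mats <- tibble::tibble(E = rep(210, nrow(mesh$tri)), nu = nu)
  sol <- assemble_solve(mesh, mats, list(f = f, fixed_dofs = fixed))
  list(mesh = mesh, stress = element_stress(mesh, mats, sol), sol = sol)
}
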