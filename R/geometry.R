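# Parametric coronal-plane proximal-femur geometry.
#
# Frame convention (right femur): head centre at the origin, +x lateral,
# +y superior, all lengths in mm.  Angles are measured in degrees
# counter-clockwise from the lateral +x axis, so the superior pole is at 90
# degrees and the weight-bearing arc [theta_med, theta_lat] runs from its
# medial end (larger angle) to its lateral end (smaller angle).

#' Geometry parameters for the parametric proximal femur
#'
#' All linear dimensions other than `head_radius` are dimensionless fractions
#' of the head radius `R`, so a single scale parameter resizes the model.
#'
#' @param head_radius Head radius `R` in mm.
#' @param neck_length Neck axis length beyond the head surface, fraction of R.
#' @param neck_width Neck width, fraction of R.
#' @param shaft_length Shaft length below the trochanteric line, fraction of R.
#' @param shaft_width Shaft width, fraction of R.
#' @param cortical_thickness Cortical shell thickness `t`, fraction of R.
#' @param neck_shaft_angle Neck-shaft (caput-collum-diaphysis) angle, degrees.
#' @param weight_bearing_arc Length-2 vector `c(theta_med, theta_lat)` in
#'   degrees; the medial end must be the larger angle.
#' @param lesion_depth_fraction Depth `d` of the necrotic wedge below the
#'   articular surface, fraction of R, in (0, 1).
#' @param c2_overhang_deg Angular overhang (degrees) by which a lesion that
#'   reaches the lateral edge of the arc extends past it.
#' @param side `"right"` or `"left"`; the left femur is the mirror image.
#' @param n_arc Number of polygon subdivisions per full circle.
#'
#' @return An object of class `coxa_params` (a validated list).
#' @export
#' @examples
#' p <- geometry_params()
#' p$head_radius
geometry_params <- function(head_radius = 25,
                            neck_length = 0.6,
                            neck_width = 0.8,
                            shaft_length = 1.6,
                            shaft_width = 1.4,
                            cortical_thickness = 0.06,
                            neck_shaft_angle = 130,
                            weight_bearing_arc = c(135, 45),
                            lesion_depth_fraction = 0.5,
                            c2_overhang_deg = 10,
                            side = c("right", "left"),
                            n_arc = 720L) {
  side <- match.arg(side)
  p <- list(
    head_radius = head_radius, neck_length = neck_length,
    neck_width = neck_width, shaft_length = shaft_length,
    shaft_width = shaft_width, cortical_thickness = cortical_thickness,
    neck_shaft_angle = neck_shaft_angle,
    weight_bearing_arc = weight_bearing_arc,
    lesion_depth_fraction = lesion_depth_fraction,
    c2_overhang_deg = c2_overhang_deg, side = side, n_arc = as.integer(n_arc)
  )
  class(p) <- "coxa_params"
  validate_geometry_params(p)
  p
}

validate_geometry_params <- function(p) {
  if (!(p$head_radius > 0)) {
    stop("invalid geometry parameters: head_radius R must satisfy R > 0",
         call. = FALSE)
  }
  if (!(p$cortical_thickness > 0 && p$cortical_thickness < 0.2)) {
    stop("invalid geometry parameters: cortical_thickness t must satisfy ",
         "0 < t < 0.2*R", call. = FALSE)
  }
  wb <- p$weight_bearing_arc
  if (!(length(wb) == 2 && wb[1] > wb[2])) {
    stop("invalid geometry parameters: weight_bearing_arc must satisfy ",
         "theta_med > theta_lat", call. = FALSE)
  }
  d <- p$lesion_depth_fraction
  if (!(d > 0 && d < 1)) {
    stop("invalid geometry parameters: lesion_depth_fraction d must satisfy ",
         "0 < d < 1", call. = FALSE)
  }
  if (!(p$neck_width > 0 && p$neck_width < 2)) {
    stop("invalid geometry parameters: neck_width must lie in (0, 2) ",
         "(fraction of R; the neck must be narrower than the head)",
         call. = FALSE)
  }
  if (!(p$neck_shaft_angle > 90 && p$neck_shaft_angle < 180)) {
    stop("invalid geometry parameters: neck_shaft_angle must lie in ",
         "(90, 180) degrees", call. = FALSE)
  }
  invisible(p)
}

#' JIC lesion classification descriptor
#'
#' The Japanese Investigation Committee taxonomy locates the necrotic lesion
#' within the weight-bearing arc by the fraction of the arc it occupies,
#' measured from the medial end: Type A at most the medial third, Type B at
#' most the medial two-thirds, Type C1 beyond two-thirds without reaching the
#' lateral edge of the arc, Type C2 beyond two-thirds and reaching it.  The
#' classes are inequalities; the default `arc_fraction` per label is the
#' representative used to build one model per class.
#'
#' @param label One of `"NORMAL"`, `"A"`, `"B"`, `"C1"`, `"C2"`.
#' @param arc_fraction Fraction of the weight-bearing arc occupied, from the
#'   medial end.  Defaults: NORMAL 0, A 1/3, B 2/3, C1 5/6, C2 1.
#' @param reaches_lateral_edge Logical; must be `TRUE` exactly for C2.
#' @return An object of class `coxa_jic`.
#' @export
#' @examples
#' jic_type("B")$arc_fraction
jic_type <- function(label = c("NORMAL", "A", "B", "C1", "C2"),
                     arc_fraction = NULL,
                     reaches_lateral_edge = NULL) {
  label <- match.arg(label)
  defaults <- c(NORMAL = 0, A = 1 / 3, B = 2 / 3, C1 = 5 / 6, C2 = 1)
  f <- if (is.null(arc_fraction)) unname(defaults[label]) else arc_fraction
  edge <- if (is.null(reaches_lateral_edge)) label == "C2" else reaches_lateral_edge
  ok <- switch(label,
    NORMAL = f == 0 && !edge,
    A = f > 0 && f <= 1 / 3 && !edge,
    B = f > 1 / 3 && f <= 2 / 3 && !edge,
    C1 = f > 2 / 3 && !edge,
    C2 = f > 2 / 3 && edge
  )
  if (!ok) {
    stop(sprintf(
      "invalid JIC descriptor: label %s is inconsistent with arc_fraction %.4g and reaches_lateral_edge %s",
      label, f, edge
    ), call. = FALSE)
  }
  structure(list(label = label, arc_fraction = f, reaches_lateral_edge = edge),
            class = "coxa_jic")
}

# Internal: derived scalar frame quantities shared by geometry and meshing.
geometry_frame <- function(p) {
  R <- p$head_radius
  t <- p$cortical_thickness * R
  phi <- p$neck_shaft_angle - 180          # neck axis direction, degrees
  gamma <- asin(p$neck_width / 2) * 180 / pi  # junction half-angle at the head
  a_med <- phi - gamma                      # medial junction corner angle
  a_lat <- phi + gamma                      # lateral junction corner angle
  u <- c(cos(phi * pi / 180), sin(phi * pi / 180))
  troch <- (R + p$neck_length * R) * u      # trochanteric line centre
  wsh <- p$shaft_width * R / 2
  y_d <- troch[2] - p$shaft_length * R      # distal cut level
  A_med <- R * c(cos(a_med * pi / 180), sin(a_med * pi / 180))
  A_lat <- R * c(cos(a_lat * pi / 180), sin(a_lat * pi / 180))
  list(
    R = R, t = t, phi = phi, a_med = a_med, a_lat = a_lat,
    A_med = A_med, A_lat = A_lat,
    medial_border = rbind(A_med, c(troch[1] - wsh, troch[2]), c(troch[1] - wsh, y_d)),
    lateral_border = rbind(A_lat, c(troch[1] + wsh, troch[2]), c(troch[1] + wsh, y_d)),
    troch = troch, y_distal = y_d,
    theta_med = p$weight_bearing_arc[1], theta_lat = p$weight_bearing_arc[2]
  )
}

mirror_x <- function(poly) {
  poly[, 1] <- -poly[, 1]
  poly[rev(seq_len(nrow(poly))), , drop = FALSE]
}

#' Build the intact proximal-femur geometry
#'
#' Constructs the closed outer boundary (head disk merged with neck and
#' shaft), the cortical shell tracking the outer boundary, and the trabecular
#' interior.  The construction is a pure function of its parameters: repeated
#' calls return identical vertex lists.
#'
#' @param params A [geometry_params()] object.
#' @return An object of class `coxa_geometry` with the outline polygon, a
#'   `regions` list of labelled polygons (`cortical`, `trabecular`,
#'   `necrotic`), the weight-bearing arc, and internal frame data used by the
#'   mesher.
#' @export
#' @examples
#' geom <- build_outline(geometry_params())
#' nrow(geom$outline)
build_outline <- function(params) {
  stopifnot(inherits(params, "coxa_params"))
  validate_geometry_params(params)
  fr <- geometry_frame(params)
  n_arc <- params$n_arc
  step <- 360 / n_arc

  # Outer boundary: articular arc CCW from the lateral junction corner around
  # the head to the medial corner, then medial border, distal cut, lateral
  # border back to the start.
  span <- (fr$a_med + 360) - fr$a_lat
  n_art <- max(16L, ceiling(span / step))
  th <- seq(fr$a_lat, fr$a_med + 360, length.out = n_art + 1L) * pi / 180
  arc <- cbind(fr$R * cos(th), fr$R * sin(th))
  mb <- fr$medial_border
  lb <- fr$lateral_border
  outline <- rbind(
    arc,                                    # A_lat ... A_med
    mb[2:3, , drop = FALSE],                # down the medial border
    lb[3:2, , drop = FALSE]                 # distal cut, up the lateral border
  )

  regions <- list(
    cortical = c(
      list(annular_sector(fr$R - fr$t, fr$R, fr$a_lat, fr$a_med + 360, n = n_art)),
      stem_cortex_polys(fr)
    ),
    trabecular = c(
      list(annular_sector(0, fr$R - fr$t, 0, 360, n = n_arc)),
      list(annular_sector(fr$R - fr$t, fr$R, fr$a_med, fr$a_lat,
                          n = max(8L, ceiling((fr$a_lat - fr$a_med) / step)))),
      list(stem_interior_poly(fr))
    ),
    necrotic = list()
  )

  geom <- list(
    params = params, frame = fr, outline = outline, regions = regions,
    weight_bearing_arc = params$weight_bearing_arc,
    arc_endpoints = rbind(
      fr$R * c(cos(fr$theta_med * pi / 180), sin(fr$theta_med * pi / 180)),
      fr$R * c(cos(fr$theta_lat * pi / 180), sin(fr$theta_lat * pi / 180))
    ),
    lesion = NULL
  )
  class(geom) <- "coxa_geometry"
  if (params$side == "left") geom <- mirror_geometry(geom)
  geom
}

# Offset a 3-point border polyline into the stem by distance d (miter joins).
offset_border <- function(pl, d, inward_sign) {
  segs <- diff(pl)
  nrm <- cbind(-segs[, 2], segs[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2)) * inward_sign
  p1 <- pl[1, ] + d * nrm[1, ]
  p3 <- pl[3, ] + d * nrm[2, ]
  # miter point: intersection of the two offset lines at the middle vertex
  a1 <- pl[1, ] + d * nrm[1, ]; dir1 <- segs[1, ]
  a2 <- pl[2, ] + d * nrm[2, ]; dir2 <- segs[2, ]
  M <- cbind(dir1, -dir2)
  p2 <- if (abs(det(M)) < 1e-12) {
    pl[2, ] + d * (nrm[1, ] + nrm[2, ]) / 2
  } else {
    tt <- solve(M, a2 - a1)
    a1 + tt[1] * dir1
  }
  rbind(p1, p2, p3)
}

stem_cortex_polys <- function(fr) {
  med_in <- offset_border(fr$medial_border, fr$t, inward_sign = +1)
  lat_in <- offset_border(fr$lateral_border, fr$t, inward_sign = -1)
  list(
    rbind(fr$medial_border, med_in[3:1, , drop = FALSE]),
    rbind(lat_in, fr$lateral_border[3:1, , drop = FALSE])
  )
}

stem_interior_poly <- function(fr) {
  med_in <- offset_border(fr$medial_border, fr$t, inward_sign = +1)
  lat_in <- offset_border(fr$lateral_border, fr$t, inward_sign = -1)
  rbind(lat_in[3:1, , drop = FALSE], med_in)
}

mirror_geometry <- function(geom) {
  geom$outline <- mirror_x(geom$outline)
  geom$regions <- lapply(geom$regions, function(polys) lapply(polys, mirror_x))
  geom$arc_endpoints[, 1] <- -geom$arc_endpoints[, 1]
  geom
}

#' Carve a JIC-classified necrotic wedge into the geometry
#'
#' The necrotic region is an annular wedge touching the articular surface:
#' radii in `[R (1 - d), R]`, angular span the fraction `f` of the
#' weight-bearing arc measured from its medial end.  A lesion that reaches the
#' lateral edge of the arc (Type C2) extends past it by the configured
#' overhang.  The wedge is removed from the cortical and trabecular regions.
#'
#' @param geom An intact [build_outline()] geometry (no lesion yet).
#' @param jic A [jic_type()] descriptor.
#' @param d Depth fraction; defaults to the geometry's
#'   `lesion_depth_fraction`.
#' @param spare_shell If `TRUE` (default) the wedge stops at the inner shell
#'   surface (radius `R - t`): in pre-collapse disease the subchondral
#'   cortical plate is still structurally intact, and it is precisely the
#'   intact plate's overload that the load share ratio measures.  Set to
#'   `FALSE` to carve the wedge through the shell to the articular surface.
#' @return A new `coxa_geometry` with the `necrotic` region populated.
#' @export
#' @examples
#' geom <- build_outline(geometry_params())
#' les <- carve_lesion(geom, jic_type("B"))
#' les$lesion$label
carve_lesion <- function(geom, jic, d = NULL, spare_shell = TRUE) {
  stopifnot(inherits(geom, "coxa_geometry"))
  if (!is.null(geom$lesion)) {
    stop("geometry already carries a lesion; carve into an intact geometry",
         call. = FALSE)
  }
  if (!inherits(jic, "coxa_jic")) {
    if (is.list(jic) && identical(jic$label, "NORMAL") &&
        isTRUE(jic$arc_fraction > 0)) {
      stop("contract violation: cannot carve a lesion with arc_fraction > 0 ",
           "into a NORMAL head", call. = FALSE)
    }
    stop("jic must be a jic_type() descriptor", call. = FALSE)
  }
  if (jic$label == "NORMAL") {
    geom$lesion <- list(label = "NORMAL", arc_fraction = 0,
                        a1 = NA_real_, a2 = NA_real_,
                        r_in = NA_real_, r_out = NA_real_, area = 0)
    return(geom)
  }
  p <- geom$params
  fr <- geom$frame
  if (is.null(d)) d <- p$lesion_depth_fraction
  if (!(d > 0 && d < 1)) {
    stop("invalid lesion depth: d must satisfy 0 < d < 1", call. = FALSE)
  }
  W <- fr$theta_med - fr$theta_lat
  a2 <- fr$theta_med
  a1 <- fr$theta_med - jic$arc_fraction * W
  if (jic$reaches_lateral_edge) a1 <- min(a1, fr$theta_lat) - p$c2_overhang_deg
  r_out <- if (spare_shell) fr$R - fr$t else fr$R
  r_in <- fr$R * (1 - d)
  if (r_in >= r_out) {
    stop("invalid lesion depth: wedge floor at or above its ceiling ",
         "(d too small relative to the cortical thickness)", call. = FALSE)
  }
  n_wed <- max(8L, ceiling((a2 - a1) / (360 / p$n_arc)))
  wedge <- annular_sector(r_in, r_out, a1, a2, n = n_wed)
  if (p$side == "left") wedge <- mirror_x(wedge)

  geom$lesion <- list(
    label = jic$label, arc_fraction = jic$arc_fraction,
    reaches_lateral_edge = jic$reaches_lateral_edge,
    a1 = a1, a2 = a2, r_in = r_in, r_out = r_out,
    area = (a2 - a1) * pi / 180 / 2 * (r_out^2 - r_in^2)
  )
  geom$regions$necrotic <- list(wedge)
  geom$regions <- subtract_wedge_from_regions(geom)
  geom
}

# Rebuild cortical/trabecular export polygons with the wedge notched out.
subtract_wedge_from_regions <- function(geom) {
  p <- geom$params
  fr <- geom$frame
  les <- geom$lesion
  step <- 360 / p$n_arc
  n_of <- function(a, b) max(8L, ceiling((b - a) / step))
  regions <- geom$regions

  shell_pieces <- list()
  art_lo <- fr$a_lat
  art_hi <- fr$a_med + 360
  if (les$r_out > fr$R - fr$t + 1e-9) {
    # wedge reaches into the shell: shell notched over [a1, a2]
    if (les$a1 > art_lo) {
      shell_pieces <- c(shell_pieces, list(
        annular_sector(fr$R - fr$t, fr$R, art_lo, les$a1, n = n_of(art_lo, les$a1))
      ))
    }
    if (art_hi > les$a2) {
      shell_pieces <- c(shell_pieces, list(
        annular_sector(fr$R - fr$t, fr$R, les$a2, art_hi, n = n_of(les$a2, art_hi))
      ))
    }
  } else {
    shell_pieces <- list(annular_sector(fr$R - fr$t, fr$R, art_lo, art_hi,
                                        n = n_of(art_lo, art_hi)))
  }

  # trabecular head disk with the wedge part below the shell notched out
  ri <- fr$R - fr$t
  w_lo <- les$a1
  w_hi <- les$a2
  w_floor <- les$r_in
  if (w_floor < ri) {
    n1 <- n_of(w_hi, w_lo + 360)
    n2 <- n_of(w_lo, w_hi)
    th_out <- seq(w_hi, w_lo + 360, length.out = n1 + 1L) * pi / 180
    th_in <- seq(w_hi, w_lo, length.out = n2 + 1L) * pi / 180
    disk_notched <- rbind(
      cbind(ri * cos(th_out), ri * sin(th_out)),        # big arc at R - t
      cbind(w_floor * cos(rev(th_in)), w_floor * sin(rev(th_in)))  # wedge floor
    )
    trab_head <- list(disk_notched)
  } else {
    trab_head <- list(annular_sector(0, ri, 0, 360, n = p$n_arc))
  }

  junction_band <- list(annular_sector(ri, fr$R, fr$a_med, fr$a_lat,
                                       n = n_of(fr$a_med, fr$a_lat)))
  stem <- list(stem_interior_poly(fr))
  regions$cortical <- c(shell_pieces, stem_cortex_polys(fr))
  regions$trabecular <- c(trab_head, junction_band, stem)
  if (p$side == "left") {
    keep <- regions$necrotic  # already mirrored at carve time
    regions <- lapply(regions, function(polys) lapply(polys, mirror_x))
    regions$necrotic <- keep
  }
  regions
}

# Vectorised distance from points to a polyline.
dist_to_polyline <- function(px, py, pl) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(pl) - 1L)) {
    ax <- pl[i, 1]; ay <- pl[i, 2]
    bx <- pl[i + 1L, 1]; by <- pl[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d <- pmin(d, sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2))
  }
  d
}

#' Classify points into tissue regions
#'
#' Membership is evaluated against the exact parametric primitives (circle
#' radii, angular spans, border offsets), not the discretised export polygons,
#' so classification is independent of polygon resolution.  Priority:
#' necrotic, then cortical, then trabecular.
#'
#' @param geom A `coxa_geometry`.
#' @param px,py Numeric vectors of query coordinates (mm).
#' @return Character vector with values `"cortical"`, `"trabecular"`,
#'   `"necrotic"`, or `NA` for points outside the domain.
#' @export
region_label <- function(geom, px, py) {
  p <- geom$params
  fr <- geom$frame
  if (p$side == "left") px <- -px
  out <- rep(NA_character_, length(px))
  r <- sqrt(px^2 + py^2)
  th <- atan2(py, px) * 180 / pi
  thn <- ((th - fr$a_lat) %% 360) + fr$a_lat  # in [a_lat, a_lat + 360)
  in_head <- r <= fr$R
  articular <- thn <= fr$a_med + 360

  les <- geom$lesion
  if (!is.null(les) && les$label != "NORMAL") {
    in_wedge <- in_head & r >= les$r_in & r <= les$r_out &
      thn >= les$a1 & thn <= les$a2
    out[in_wedge] <- "necrotic"
  }
  shell <- in_head & is.na(out) & r >= fr$R - fr$t & articular
  out[shell] <- "cortical"
  out[in_head & is.na(out)] <- "trabecular"

  # stem: outside the head circle, inside the stem boundary polygon
  cand <- which(!in_head)
  if (length(cand)) {
    stem_poly <- rbind(
      annular_sector(0, fr$R, fr$a_med, fr$a_lat, n = 64L)[-1, , drop = FALSE],
      fr$lateral_border[2:3, , drop = FALSE],
      fr$medial_border[3:2, , drop = FALSE]
    )
    ins <- points_in_poly(px[cand], py[cand], stem_poly)
    idx <- cand[ins]
    if (length(idx)) {
      dmin <- pmin(
        dist_to_polyline(px[idx], py[idx], fr$medial_border),
        dist_to_polyline(px[idx], py[idx], fr$lateral_border)
      )
      out[idx] <- ifelse(dmin <= fr$t, "cortical", "trabecular")
    }
  }
  out
}

#' @export
print.coxa_geometry <- function(x, ...) {
  p <- x$params
  cat("<coxa_geometry>", p$side, "femur, R =", p$head_radius, "mm\n")
  cat("  weight-bearing arc:", paste(p$weight_bearing_arc, collapse = " to "),
      "deg; cortical t =", p$cortical_thickness * p$head_radius, "mm\n")
  if (is.null(x$lesion)) {
    cat("  lesion: none (intact)\n")
  } else {
    cat("  lesion:", x$lesion$label,
        if (x$lesion$label != "NORMAL") {
          sprintf("(span %.1f to %.1f deg, area %.1f mm^2)",
                  x$lesion$a1, x$lesion$a2, x$lesion$area)
        } else "(empty wedge)", "\n")
  }
  invisible(x)
}

#' Specification of the S1 and S2 evaluation regions
#'
#' S1 is the subchondral cortical band of the weight-bearing arc: the shell
#' route that load takes when it bypasses a damaged trabecular path, so its
#' average stress registers the bypass for medial and lateral lesions alike.
#' S2 is a straight trabecular corridor from the centroid of the
#' weight-bearing arc down to the medial calcar, the principal compressive
#' stress-transfer band.  Both are defined on the intact anatomy so lesioned
#' and normal models are averaged over identical regions.
#'
#' @param s1_arc Angular span of S1 in degrees `c(lo, hi)`; default the full
#'   weight-bearing arc.  `c(45, 90)` restricts it to the lateral half (the
#'   strict superolateral-column reading).
#' @param corridor_halfwidth Corridor half-width as a fraction of R.
#' @return An object of class `coxa_region_spec`.
#' @export
region_spec <- function(s1_arc = NULL, corridor_halfwidth = 0.3) {
  if (!(corridor_halfwidth >= 0)) {
    stop("corridor_halfwidth must be non-negative", call. = FALSE)
  }
  structure(list(s1_arc = s1_arc, corridor_halfwidth = corridor_halfwidth),
            class = "coxa_region_spec")
}

#' Build the S1/S2 region mask polygons
#'
#' @param geom A `coxa_geometry` (lesioned or intact; masks depend only on
#'   the intact anatomy).
#' @param spec A [region_spec()].
#' @return A list with polygons `S1` and `S2`.
#' @export
#' @examples
#' masks <- region_masks(build_outline(geometry_params()), region_spec())
#' names(masks)
region_masks <- function(geom, spec = region_spec()) {
  stopifnot(inherits(geom, "coxa_geometry"))
  p <- geom$params
  fr <- geom$frame
  s1_arc <- spec$s1_arc
  if (is.null(s1_arc)) {
    s1_arc <- c(fr$theta_lat, fr$theta_med)
  }
  n1 <- max(16L, ceiling((s1_arc[2] - s1_arc[1]) / (360 / p$n_arc)))
  S1 <- annular_sector(fr$R - fr$t, fr$R, s1_arc[1], s1_arc[2], n = n1)

  mid <- (fr$theta_med + fr$theta_lat) / 2 * pi / 180
  P1 <- fr$R * c(cos(mid), sin(mid))     # weight-bearing arc centroid
  P2 <- fr$A_med                         # medial calcar corner
  w <- spec$corridor_halfwidth * fr$R
  axis <- P2 - P1
  axis <- axis / sqrt(sum(axis^2))
  nrm <- c(-axis[2], axis[1])
  corridor <- rbind(P1 + w * nrm, P1 - w * nrm, P2 - w * nrm, P2 + w * nrm)
  if (poly_area(corridor) < 0) corridor <- corridor[4:1, ]
  inner_disk <- annular_sector(0, fr$R - fr$t, 0, 360, n = p$n_arc)[-1, , drop = FALSE]
  S2 <- clip_convex(inner_disk, corridor)
  if (nrow(S2) < 3L) {
    stop("configuration error: S2 corridor has empty intersection with the ",
         "trabecular interior", call. = FALSE)
  }
  if (p$side == "left") {
    S1 <- mirror_x(S1)
    S2 <- mirror_x(S2)
  }
  list(S1 = S1, S2 = S2)
}
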