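# Plain-text (YAML) configuration round-trip for the grid specification.

#' Default pipeline configuration
#'
#' Nested list mirroring [grid_spec()]; every value can be overridden in a
#' YAML config file.
#'
#' @return A named list.
#' @export
default_config <- function() {
  spec <- grid_spec()
  list(
    grid = list(
      conditions = spec$conditions,
      betas = spec$betas,
      mesh_h = spec$h,
      seed = spec$seed
    ),
    geometry = unclass(spec$params)[setdiff(names(spec$params), NULL)],
    materials = as.list(stats::setNames(spec$materials$E, paste0("E_", spec$materials$tissue))) |>
      c(list(nu = spec$materials$nu[1])),
    load = list(J = spec$J, theta_c0 = spec$theta_c0,
                halfwidth = spec$halfwidth),
    muscles = purrr::transpose(as.list(muscle_table())) |>
      stats::setNames(muscle_table()$muscle) |>
      lapply(function(m) m[setdiff(names(m), "muscle")]),
    metrics = list(
      tau_frac = spec$tau_frac,
      measure = spec$measure,
      pct_reference = spec$pct_reference,
      corridor_halfwidth = spec$regions$corridor_halfwidth,
      spare_shell = spec$spare_shell
    )
  )
}

#' Write a configuration to a YAML file
#' @param config Configuration list, see [default_config()].
#' @param path Output file path.
#' @export
write_config <- function(config = default_config(), path) {
  yaml::write_yaml(config, path, precision = 12L)
  invisible(path)
}

#' Read a configuration file and build the grid specification
#'
#' Missing keys fall back to the defaults, so a config file only needs the
#' values it overrides.
#'
#' @param path YAML config file path, or `NULL` for pure defaults.
#' @return A [grid_spec()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  geo <- cfg$geometry
  params <- geometry_params(
    head_radius = geo$head_radius, neck_length = geo$neck_length,
    neck_width = geo$neck_width, shaft_length = geo$shaft_length,
    shaft_width = geo$shaft_width,
    cortical_thickness = geo$cortical_thickness,
    neck_shaft_angle = geo$neck_shaft_angle,
    weight_bearing_arc = unlist(geo$weight_bearing_arc),
    lesion_depth_fraction = geo$lesion_depth_fraction,
    c2_overhang_deg = geo$c2_overhang_deg,
    side = geo$side, n_arc = geo$n_arc
  )
  mats <- material_table(
    E_cortical = cfg$materials$E_cortical,
    E_trabecular = cfg$materials$E_trabecular,
    E_necrotic = cfg$materials$E_necrotic,
    nu = cfg$materials$nu
  )
  mus <- dplyr::bind_rows(purrr::imap(cfg$muscles, function(m, name) {
    tibble::tibble(muscle = name, force_N = m$force_N, part = m$part,
                   frac = m$frac, dir_x = m$dir_x, dir_y = m$dir_y)
  }))
  grid_spec(
    conditions = unlist(cfg$grid$conditions),
    betas = unlist(cfg$grid$betas),
    params = params, materials = mats,
    regions = region_spec(corridor_halfwidth = cfg$metrics$corridor_halfwidth),
    muscles = mus,
    J = cfg$load$J, theta_c0 = cfg$load$theta_c0,
    halfwidth = cfg$load$halfwidth,
    h = cfg$grid$mesh_h, tau_frac = cfg$metrics$tau_frac,
    measure = cfg$metrics$measure, pct_reference = cfg$metrics$pct_reference,
    spare_shell = isTRUE(cfg$metrics$spare_shell),
    seed = cfg$grid$seed
  )
}
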