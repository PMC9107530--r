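# Orchestration of the parametric sweep: 5 lesion conditions x 6 abduction
# angles = 30 models, solved and reduced to the tidy result table.

#' Specification of the parametric model grid
#'
#' @param conditions Character vector of JIC conditions; the normal head must
#'   be included because it provides every reference.
#' @param betas Abduction angles in degrees.
#' @param params Shared [geometry_params()].
#' @param materials Tissue material table, [material_table()].
#' @param regions S1/S2 [region_spec()].
#' @param muscles Muscle table, [muscle_table()].
#' @param J,theta_c0,halfwidth Joint load parameters, see [joint_pressure()].
#' @param h Target mesh edge length (mm).
#' @param tau_frac Active-area threshold fraction, see [active_area()].
#' @param measure Region-average stress measure, `"pcs"` or `"vonmises"`.
#' @param pct_reference Whether percent change compares against the normal
#'   model at the same beta (default) or at beta = 0.
#' @param spare_shell Passed to [carve_lesion()].
#' @param seed Recorded for provenance; the pipeline is deterministic and
#'   draws no random numbers.
#' @return An object of class `coxa_grid_spec`.
#' @export
#' @examples
#' spec <- grid_spec()
#' length(spec$conditions) * length(spec$betas)
grid_spec <- function(conditions = c("NORMAL", "A", "B", "C1", "C2"),
                      betas = c(0, 10, 15, 20, 25, 30),
                      params = geometry_params(),
                      materials = material_table(),
                      regions = region_spec(),
                      muscles = muscle_table(),
                      J = 1600, theta_c0 = 74, halfwidth = 30,
                      h = 1.0, tau_frac = 0.3,
                      measure = c("pcs", "vonmises"),
                      pct_reference = c("same_beta", "beta0"),
                      spare_shell = TRUE,
                      seed = 1L) {
  measure <- match.arg(measure)
  pct_reference <- match.arg(pct_reference)
  bad <- setdiff(conditions, jic_severity_order)
  if (length(bad)) {
    stop("unknown conditions: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!("NORMAL" %in% conditions)) {
    stop("sequencing error: the NORMAL condition must be part of the grid ",
         "(it is the reference for percent change, active area and ",
         "classification)", call. = FALSE)
  }
  structure(list(
    conditions = unique(conditions), betas = sort(unique(betas)),
    params = params, materials = materials, regions = regions,
    muscles = muscles, J = J, theta_c0 = theta_c0, halfwidth = halfwidth,
    h = h, tau_frac = tau_frac, measure = measure,
    pct_reference = pct_reference, spare_shell = spare_shell,
    seed = as.integer(seed)
  ), class = "coxa_grid_spec")
}

#' Run the parametric model grid
#'
#' Builds the geometry, mesh, materials and stiffness once per condition,
#' solves all abduction angles against the factorised operator, and reduces
#' every cell to the result-table row.  Normal-head cells are computed first:
#' they provide the PCS reference scale, the percent-change baseline and the
#' classification references.
#'
#' @param spec A [grid_spec()].
#' @param vtk_dir Optional directory; when given, each cell's displacement
#'   and stress fields are written as VTK legacy unstructured-grid files.
#' @param quiet Suppress per-cell progress lines.
#' @return A tibble of class `coxa_grid_result`, one row per grid cell, with
#'   metrics (`S1_avg_MPa`, `S2_avg_MPa`, `LSR`, `pct_change`,
#'   `active_area_fraction`, `classified_as`) and provenance (`n_elements`,
#'   `residual`, `config_hash`, ...).  The spec and the beta = 0 reference
#'   table are attached as attributes.
#' @export
#' @examples
#' \donttest{
#' res <- run_grid(grid_spec(conditions = c("NORMAL", "B"), betas = c(0, 30),
#'                           h = 1.0))
#' res[, c("condition", "beta_deg", "LSR")]
#' }
run_grid <- function(spec = grid_spec(), vtk_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(spec, "coxa_grid_spec"))
  conditions <- unique(c("NORMAL", spec$conditions))
  hash <- rlang::hash(spec[setdiff(names(spec), "seed")])
  intact <- build_outline(spec$params)
  masks <- region_masks(intact, spec$regions)
  R <- spec$params$head_radius

  cells <- list()
  stress_store <- list()
  ref_pcs <- NA_real_
  for (cond in conditions) {
    geom <- carve_lesion(build_outline(spec$params), jic_type(cond),
                         spare_shell = spec$spare_shell)
    mesh <- triangulate(geom, h = spec$h, seed = spec$seed)
    mats <- assign_materials(mesh, geom, spec$materials)
    K <- assemble_stiffness(mesh, mats)
    for (beta in spec$betas) {
      lc <- load_case(mesh, beta = beta, J = spec$J,
                      theta_c0 = spec$theta_c0, halfwidth = spec$halfwidth,
                      muscles = spec$muscles)
      sol <- tryCatch(
        assemble_solve(mesh, mats, lc, K = K),
        error = function(e) {
          stop(sprintf("grid cell (%s, beta = %g) failed: %s",
                       cond, beta, conditionMessage(e)), call. = FALSE)
        }
      )
      if (sol$residual > 1e-8) {
        stop(sprintf(
          "grid cell (%s, beta = %g): solver residual %.3g exceeds 1e-8",
          cond, beta, sol$residual
        ), call. = FALSE)
      }
      stress <- principal_decompose(element_stress(mesh, mats, sol))
      if (cond == "NORMAL" && beta == spec$betas[1] && is.na(ref_pcs)) {
        ref_pcs <- pcs_reference(stress, R)
      }
      row <- lsr(stress, masks, measure = spec$measure)
      row$condition <- cond
      row$beta_deg <- beta
      row$active_area_fraction <- active_area(stress, R, ref_pcs,
                                              tau_frac = spec$tau_frac)
      row$n_elements <- nrow(mesh$tri)
      row$n_nodes <- nrow(mesh$nodes)
      row$mesh_h <- spec$h
      row$residual <- sol$residual
      row$config_hash <- hash
      row$seed <- spec$seed
      cells[[paste(cond, beta)]] <- row
      if (!quiet) {
        message(sprintf("[%s beta=%2g] n_el=%d residual=%.2e LSR=%.4f",
                        cond, beta, nrow(mesh$tri), sol$residual, row$LSR))
      }
      if (!is.null(vtk_dir)) {
        dir.create(vtk_dir, recursive = TRUE, showWarnings = FALSE)
        write_vtk(mesh, file.path(vtk_dir, sprintf("%s_beta%02d.vtk", cond, beta)),
                  point_data = list(displacement = sol$U),
                  cell_data = list(sxx = stress$sxx, syy = stress$syy,
                                   sxy = stress$sxy, pcs = stress$pcs))
      }
    }
  }
  tbl <- dplyr::bind_rows(cells)

  # percent change against the normal model
  norm <- tbl[tbl$condition == "NORMAL", c("beta_deg", "LSR")]
  names(norm)[2] <- "LSR_normal"
  if (spec$pct_reference == "beta0") {
    norm$LSR_normal <- norm$LSR_normal[norm$beta_deg == min(norm$beta_deg)]
  }
  tbl <- dplyr::left_join(tbl, norm, by = "beta_deg")
  tbl$pct_change <- percent_change(tbl$LSR, tbl$LSR_normal)
  tbl$LSR_normal <- NULL

  # classification against the beta = 0 references
  b0 <- min(spec$betas)
  reference <- tbl[tbl$beta_deg == b0, c("condition", "active_area_fraction")]
  tbl$classified_as <- vapply(tbl$active_area_fraction, classify_pattern,
                              character(1), reference = reference)
  tbl <- tbl[order(match(tbl$condition, jic_severity_order), tbl$beta_deg),
             c("condition", "beta_deg", "S1_avg_MPa", "S2_avg_MPa", "LSR",
               "pct_change", "active_area_fraction", "classified_as",
               "n_elements", "n_nodes", "mesh_h", "residual", "seed",
               "config_hash")]
  attr(tbl, "spec") <- spec
  attr(tbl, "reference") <- reference
  attr(tbl, "reference_pcs") <- ref_pcs
  class(tbl) <- c("coxa_grid_result", class(tbl))
  tbl
}

#' Trend verdicts of a grid result
#'
#' Evaluates the qualitative laws the model family is built to probe: the
#' severity ordering of LSR and active area across lesion types at rest, the
#' recovery of the load share ratio under abduction for Types B and C1, the
#' persistent elevation for Type C2, the reclassification of Type B to a
#' healthier pattern, and active-area growth with abduction for every
#' lesioned condition.
#'
#' @param result A `coxa_grid_result`.
#' @param c2_threshold Materiality threshold (percent) that Type C2's percent
#'   change must still exceed at maximal abduction.
#' @return A tibble with columns `check`, `passed`, `detail`.
#' @export
trend_checks <- function(result, c2_threshold = 10) {
  b0 <- min(result$beta_deg)
  bmax <- max(result$beta_deg)
  at <- function(cond, beta, col) {
    result[[col]][result$condition == cond & result$beta_deg == beta]
  }
  present <- intersect(jic_severity_order, unique(result$condition))
  lsr0 <- vapply(present, at, numeric(1), beta = b0, col = "LSR")
  aa0 <- vapply(present, at, numeric(1), beta = b0,
                col = "active_area_fraction")

  checks <- list()
  lesioned <- setdiff(present, "NORMAL")
  if (length(present) == 5L) {
    checks$lsr_ordering_beta0 <- list(
      passed = lsr0[["NORMAL"]] <= lsr0[["A"]] && lsr0[["A"]] < lsr0[["B"]] &&
        lsr0[["B"]] < lsr0[["C1"]] && lsr0[["C1"]] < lsr0[["C2"]],
      detail = paste(sprintf("%s=%.4f", names(lsr0), lsr0), collapse = " ")
    )
    checks$active_area_ordering_beta0 <- list(
      passed = all(diff(aa0) < 0),
      detail = paste(sprintf("%s=%.4f", names(aa0), aa0), collapse = " ")
    )
  }
  for (cond in intersect(c("B", "C1"), present)) {
    checks[[paste0("recovery_", cond)]] <- list(
      passed = abs(at(cond, bmax, "pct_change")) <
        abs(at(cond, b0, "pct_change")),
      detail = sprintf("pct %.2f%% at beta=%g vs %.2f%% at beta=%g",
                       at(cond, bmax, "pct_change"), bmax,
                       at(cond, b0, "pct_change"), b0)
    )
  }
  if ("C2" %in% present) {
    checks$c2_persistent_elevation <- list(
      passed = at("C2", bmax, "pct_change") > c2_threshold,
      detail = sprintf("pct %.2f%% at beta=%g (threshold %g%%)",
                       at("C2", bmax, "pct_change"), bmax, c2_threshold)
    )
  }
  if ("B" %in% present) {
    sev <- function(lab) match(lab, jic_severity_order)
    checks$b_reclassifies_healthier <- list(
      passed = sev(at("B", bmax, "classified_as")) <
        sev(at("B", b0, "classified_as")),
      detail = sprintf("B classifies as %s at beta=%g vs %s at beta=%g",
                       at("B", bmax, "classified_as"), bmax,
                       at("B", b0, "classified_as"), b0)
    )
  }
  if (length(lesioned)) {
    growth <- vapply(lesioned, function(cond) {
      at(cond, bmax, "active_area_fraction") > at(cond, b0,
                                                  "active_area_fraction")
    }, logical(1))
    checks$active_area_grows_with_abduction <- list(
      passed = all(growth),
      detail = paste(sprintf("%s:%s", names(growth), growth), collapse = " ")
    )
  }
  tibble::tibble(
    check = names(checks),
    passed = vapply(checks, `[[`, logical(1), "passed"),
    detail = vapply(checks, `[[`, character(1), "detail")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.coxa_grid_result <- function(x, ...) {
  tibble::as_tibble(x[, c("condition", "beta_deg", "S1_avg_MPa", "S2_avg_MPa",
                          "LSR", "pct_change", "active_area_fraction",
                          "classified_as")])
}

#' @export
glance.coxa_grid_result <- function(x, ...) {
  ck <- trend_checks(x)
  wide <- stats::setNames(as.list(ck$passed), ck$check)
  dplyr::bind_cols(
    tibble::tibble(
      n_models = nrow(x),
      n_conditions = length(unique(x$condition)),
      n_betas = length(unique(x$beta_deg)),
      max_residual = max(x$residual)
    ),
    tibble::as_tibble(wide)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Load-share-ratio curves across abduction angles
#' @param object A `coxa_grid_result`.
#' @param ... Unused.
#' @return A ggplot object, one LSR-vs-beta curve per condition.
#' @export
autoplot.coxa_grid_result <- function(object, ...) {
  d <- tidy(object)
  d$condition <- factor(d$condition, levels = jic_severity_order)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_deg, y = .data$LSR,
                                  colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "abduction angle (degrees)", y = "load share ratio S1/S2",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Active-area fraction across abduction angles
#' @param result A `coxa_grid_result`.
#' @return A ggplot object.
#' @export
plot_active_area <- function(result) {
  d <- tidy(result)
  d$condition <- factor(d$condition, levels = jic_severity_order)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_deg,
                                  y = .data$active_area_fraction,
                                  colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "abduction angle (degrees)",
                  y = "PCS active-area fraction", colour = "condition") +
    ggplot2::theme_minimal()
}

#' Condition-by-angle classification matrix
#' @param result A `coxa_grid_result`.
#' @return A ggplot tile plot of `classified_as`.
#' @export
plot_classification <- function(result) {
  d <- tidy(result)
  d$condition <- factor(d$condition, levels = rev(jic_severity_order))
  d$classified_as <- factor(d$classified_as, levels = jic_severity_order)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$beta_deg),
                                  y = .data$condition,
                                  fill = .data$classified_as)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$classified_as), size = 3) +
    ggplot2::labs(x = "abduction angle (degrees)", y = "modelled condition",
                  fill = "classifies as") +
    ggplot2::theme_minimal()
}

#' Write the result table, figures and a plain-text summary
#'
#' @param result A complete `coxa_grid_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary text lines.
#' @export
report_grid <- function(result, out_dir) {
  spec <- attr(result, "spec")
  expect <- expand.grid(condition = spec$conditions, beta_deg = spec$betas,
                        stringsAsFactors = FALSE)
  have <- paste(result$condition, result$beta_deg)
  missing <- expect[!(paste(expect$condition, expect$beta_deg) %in% have), ]
  if (nrow(missing)) {
    stop("report error: result table incomplete; missing cells: ",
         paste(sprintf("(%s, %g)", missing$condition, missing$beta_deg),
               collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(result), file.path(out_dir, "results.csv"))
  ggplot2::ggsave(file.path(out_dir, "lsr_vs_beta.png"), autoplot(result),
                  width = 6, height = 4, dpi = 150)
  ggplot2::ggsave(file.path(out_dir, "active_area_vs_beta.png"),
                  plot_active_area(result), width = 6, height = 4, dpi = 150)
  ggplot2::ggsave(file.path(out_dir, "classification_matrix.png"),
                  plot_classification(result), width = 6, height = 4, dpi = 150)
  ck <- trend_checks(result)
  lines <- c(
    sprintf("coxafem grid report: %d models (%d conditions x %d angles)",
            nrow(result), length(unique(result$condition)),
            length(unique(result$beta_deg))),
    sprintf("config hash %s, mesh h = %g mm, max residual %.3g",
            result$config_hash[1], result$mesh_h[1], max(result$residual)),
    "",
    "trend checklist:",
    sprintf("  [%s] %-35s %s", ifelse(ck$passed, "ok", "FAIL"), ck$check,
            ck$detail)
  )
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(lines)
}
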