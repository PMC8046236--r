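# Orchestration: configuration container and the track / solve / benchmark
# commands the CLI script wraps.

#' Run configuration
#'
#' Collects every tunable of the pipeline with its default, validated once.
#' All randomness in a run is routed through `seed`.
#'
#' @param voxel_size acquisition voxel size, um.
#' @param action_radius trusted displacement shell around the cell, um.
#' @param C10,D1 Neo-Hookean constants (kPa, 1/kPa).
#' @param delta nodal error threshold for convergence.
#' @param node_fraction required fraction of nodes below `delta`.
#' @param max_iter maximum outer iterations of the inverse solver.
#' @param quality radius-edge mesh quality bound.
#' @param tol_rel relative Newton residual tolerance.
#' @param bead_threshold bead detection threshold as a fraction of the global
#'   intensity maximum.
#' @param search_radius integer bead-matching search radius, voxels.
#' @param err_mode convergence error mode, see [inverse_state()].
#' @param seed integer seed recorded in run metadata.
#' @return Object of class `tfm_config`.
#' @export
tfm_config <- function(voxel_size = 0.63, action_radius = 10, C10 = 20,
                       D1 = 0.005, delta = 0.15, node_fraction = 0.90,
                       max_iter = 100, quality = 1.5, tol_rel = 1e-8,
                       bead_threshold = 0.3, search_radius = 5,
                       err_mode = "cumulative", seed = 1) {
  stopifnot(voxel_size > 0, action_radius > 0, C10 > 0, D1 > 0,
            delta > 0, delta <= 1, node_fraction > 0, node_fraction <= 1,
            max_iter >= 1, quality > 0, tol_rel > 0,
            bead_threshold > 0, bead_threshold < 1, search_radius >= 1)
  structure(list(voxel_size = voxel_size, action_radius = action_radius,
                 C10 = C10, D1 = D1, delta = delta,
                 node_fraction = node_fraction, max_iter = max_iter,
                 quality = quality, tol_rel = tol_rel,
                 bead_threshold = bead_threshold,
                 search_radius = search_radius, err_mode = err_mode,
                 seed = as.integer(seed)),
            class = "tfm_config")
}

.config_material <- function(config) neo_hookean(config$C10, config$D1)

.write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Track bead displacements between two TIFF stacks
#'
#' Reads the deformed and relaxed bead stacks, detects and refines beads in
#' the deformed stack, matches them into the relaxed stack and writes the
#' tracked displacements as CSV.
#'
#' @param config a [tfm_config()].
#' @param tiff_deformed,tiff_relaxed multi-page TIFF paths.
#' @param out_csv output CSV path (default alongside the deformed stack).
#' @return The [match_displacements()] result, invisibly.
#' @export
cmd_track <- function(config, tiff_deformed, tiff_relaxed,
                      out_csv = sub("\\.tiff?$", "_displacements.csv",
                                    tiff_deformed)) {
  stopifnot(inherits(config, "tfm_config"))
  for (p in c(tiff_deformed, tiff_relaxed))
    if (!file.exists(p)) stop("cmd_track: input file not found: ", p)
  s1 <- read_image_stack(tiff_deformed, config$voxel_size, "beads")
  s2 <- read_image_stack(tiff_relaxed, config$voxel_size, "beads")
  thr <- config$bead_threshold * max(s1$intensities)
  beads <- refine_subpixel(s1, detect_beads(s1, thr))
  sparse <- match_displacements(s1, s2, beads,
                                search_radius = config$search_radius)
  write_displacements_csv(sparse, out_csv)
  invisible(sparse)
}

#' Solve the inverse traction problem and export a run directory
#'
#' @param config a [tfm_config()].
#' @param mesh the deformed-configuration [tet_mesh()].
#' @param u_real nodal displacement field (um), e.g. from
#'   [build_displacement_field()].
#' @param out_dir run directory to create.
#' @return The final [inverse_state()], invisibly.
#' @export
cmd_solve <- function(config, mesh, u_real, out_dir) {
  stopifnot(inherits(config, "tfm_config"))
  mat <- .config_material(config)
  state <- run_inverse(mesh, u_real, mat, delta = config$delta,
                       node_fraction = config$node_fraction,
                       max_iter = config$max_iter,
                       err_mode = config$err_mode)
  tractions <- if (length(state$logV_history)) recover_tractions(state, mat)
               else state$traction_estimate
  export_results(state, tractions, out_dir)
  .write_config(config, file.path(out_dir, "config.json"))
  invisible(state)
}

#' Round-trip sphere benchmark driver
#'
#' Generates the sphere-in-prism benchmark, runs the inverse solver on its
#' synthetic measurements, and writes a report with the round-trip traction
#' error and nodal displacement error percentiles.
#'
#' @param config a [tfm_config()] (its `seed` drives the patch layout).
#' @param out_dir optional run directory for exported artifacts.
#' @param ... overrides passed to [make_sphere_benchmark()] (e.g.
#'   `element_size`, `force_scale`).
#' @return list with the benchmark, the inverse state and the report row.
#' @export
cmd_benchmark <- function(config = tfm_config(), out_dir = NULL, ...) {
  stopifnot(inherits(config, "tfm_config"))
  mat <- .config_material(config)
  bp <- make_sphere_benchmark(material = mat, seed = config$seed, ...)
  if (is.null(bp$deformed_mesh))  # geometry-only generation requested
    return(list(benchmark = bp, state = NULL, tractions = NULL,
                report = NULL))
  state <- run_inverse(bp$deformed_mesh, bp$u_real, mat,
                       delta = config$delta,
                       node_fraction = config$node_fraction,
                       max_iter = config$max_iter,
                       err_mode = config$err_mode)
  tractions <- if (length(state$logV_history)) recover_tractions(state, mat)
               else state$traction_estimate
  gt <- bp$tractions
  relL2 <- if (sum(gt$vectors^2) > 0)
    sqrt(sum((tractions$vectors - gt$vectors)^2)) / sqrt(sum(gt$vectors^2))
  else NA_real_
  cum <- nodal_error_summary(state, "all")
  surf <- nodal_error_summary(state, "surface")
  report <- data.frame(
    seed = config$seed,
    nodes = nrow(bp$mesh$nodes),
    iterations = state$iteration,
    converged = state$converged,
    traction_rel_l2 = relL2,
    err_max_pct = 100 * max(cum),
    err_p95_pct = 100 * quantile(cum, 0.95, names = FALSE),
    pct_below_1pct = 100 * mean(cum < 0.01),
    surf_err_p95_pct = 100 * quantile(surf, 0.95, names = FALSE))
  if (!is.null(out_dir)) {
    export_results(state, tractions, out_dir)
    .write_config(config, file.path(out_dir, "config.json"))
    write.csv(report, file.path(out_dir, "benchmark_report.csv"),
              row.names = FALSE)
  }
  list(benchmark = bp, state = state, tractions = tractions, report = report)
}
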