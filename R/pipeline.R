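#' Position a mesh under a hard constraint set
#'
#' Convenience wrapper around the core solve: builds the weighted
#' element-connectivity graph, partitions it by the constraint set,
#' preserves the original differential coordinates, and solves for the
#' free-node positions.
#'
#' @param mesh the original [fe_mesh()].
#' @param constraints a [constraint_set()].
#' @param epsilon weight-formula constant, see [build_graph()].
#' @param tol,max_iter,method solver controls, see [solve_positions()].
#' @return list: `mesh` (positioned [fe_mesh()]), `solve` (solver
#'   diagnostics), `system` (the [partition_system()] result).
#' @export
position_mesh <- function(mesh, constraints, epsilon = 1e-8, tol = 1e-10,
                          max_iter = NULL, method = "cg") {
  graph <- build_graph(mesh, epsilon = epsilon)
  system <- partition_system(graph, constraints$ids, mesh)
  targets <- constraints$targets[match(system$fixed_ids, constraints$ids), ,
                                 drop = FALSE]
  sol <- solve_positions(system, targets, tol = tol, max_iter = max_iter,
                         method = method)
  list(mesh = set_coords(mesh, sol$coords),
       solve = sol[c("iterations", "residual", "method")],
       system = system)
}

#' Run the full three-stage positioning pipeline
#'
#' Pre-processing (surface constraint assembly, optional extra-constraint
#' prediction), the hard-constrained Laplacian solve, and post-processing
#' repair of distorted elements, with per-stage quality reports.
#'
#' @param mesh the original [fe_mesh()] (or a path to a keyword file).
#' @param posed_surfaces list of `list(surface, coords)` pairs defining the
#'   target posture, as for [assemble_surface_constraints()].
#' @param extra_ids node IDs to add as predicted extra constraints (or a
#'   path to a one-ID-per-line file), or `NULL` for none.
#' @param k,ridge extra-constraint prediction controls
#'   ([predict_extra_nodes()]).
#' @param epsilon,tol,max_iter,method solver controls.
#' @param J_threshold,AR_threshold,max_passes repair controls
#'   ([repair_until_stable()]); `max_passes = 0` skips repair.
#' @param out_dir if non-`NULL`, writes `positioned.k`,
#'   `quality_before.csv`, `quality_after.csv` and `run_report.json` there.
#' @param verbose print stage banners with the three distortion counts.
#' @return list: `mesh` (final positioned mesh), `constraints`, `solve`
#'   diagnostics, `quality_before`, `quality_after`, `repair_passes`.
#' @export
run_position <- function(mesh, posed_surfaces, extra_ids = NULL, k = 30L,
                         ridge = 0, epsilon = 1e-8, tol = 1e-10,
                         max_iter = NULL, method = "cg",
                         J_threshold = 0.3, AR_threshold = 10,
                         max_passes = 5L, out_dir = NULL,
                         verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(mesh)) mesh <- read_keyword_mesh(mesh)
  say <- function(...) if (verbose) message(...)
  stage_counts <- function(rep)
    sprintf("J<%s: %d | J<0: %d | AR>%s: %d", format(rep$thresholds$J),
            rep$counts$n_J_below, rep$counts$n_negative_volume,
            format(rep$thresholds$AR), rep$counts$n_AR_above)

  say("[1/3] boundary constraints")
  constraints <- assemble_surface_constraints(mesh, posed_surfaces)
  if (!is.null(extra_ids)) {
    if (is.character(extra_ids)) extra_ids <- read_id_list(extra_ids)
    constraints <- predict_extra_nodes(mesh, constraints, extra_ids,
                                       k = k, ridge = ridge)
  }
  say("      ", length(constraints$ids), " constrained nodes (",
      sum(constraints$tags == "extra"), " extra)")

  say("[2/3] hard-constrained Laplacian solve")
  pos <- position_mesh(mesh, constraints, epsilon = epsilon, tol = tol,
                       max_iter = max_iter, method = method)
  q_before <- quality_report(pos$mesh, J_threshold, AR_threshold)
  say("      ", stage_counts(q_before))

  say("[3/3] mesh repair")
  if (max_passes >= 1L) {
    rep_res <- repair_until_stable(mesh, pos$mesh,
                                   J_threshold = J_threshold,
                                   AR_threshold = AR_threshold,
                                   max_passes = max_passes,
                                   constrained_ids = constraints$ids,
                                   ridge = ridge)
    final <- set_coords(pos$mesh, rep_res$coords)
    q_after <- rep_res$report
    passes <- rep_res$passes
  } else {
    final <- pos$mesh
    q_after <- q_before
    passes <- NULL
  }
  say("      ", stage_counts(q_after))
  elapsed <- proc.time()[["elapsed"]] - t0

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_keyword_mesh(final, file.path(out_dir, "positioned.k"))
    write_quality_csv(q_before, file.path(out_dir, "quality_before.csv"))
    write_quality_csv(q_after, file.path(out_dir, "quality_after.csv"))
    report <- list(
      n_constraints = length(constraints$ids),
      n_extra = sum(constraints$tags == "extra"),
      solver = pos$solve,
      quality_before = q_before$counts,
      quality_after = q_after$counts,
      repair_passes = passes,
      elapsed_seconds = elapsed)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  list(mesh = final, constraints = constraints, solve = pos$solve,
       quality_before = q_before, quality_after = q_after,
       repair_passes = passes, elapsed_seconds = elapsed)
}

#' Pose the boundary surfaces of a generated limb fixture
#'
#' Applies linear blend skinning at the given hinge angle and returns the
#' posed skin and skeleton surfaces in the form [run_position()] and
#' [assemble_surface_constraints()] expect.
#'
#' @param limb a [generate_limb()] result.
#' @param angle hinge angle in degrees.
#' @return list: `posed_surfaces` (skin + skeleton), `posed_coords` (full
#'   LBS-posed node matrix), `skin`, `skeleton` (the surface sets).
#' @export
pose_limb_surfaces <- function(limb, angle) {
  arm <- bend_armature(limb$armature, angle)
  posed <- pose_lbs(limb$mesh$coords, arm, limb$weights)
  skin <- extract_surface(limb$mesh, limb$parts$skin, name = "skin")
  bone <- extract_surface(limb$mesh, limb$parts$bone, name = "skeleton")
  sub <- function(surf) posed[node_index(limb$mesh, surf$node_ids), ,
                              drop = FALSE]
  list(posed_surfaces = list(list(surface = skin, coords = sub(skin)),
                             list(surface = bone, coords = sub(bone))),
       posed_coords = posed, skin = skin, skeleton = bone)
}

#' Load a pipeline run configuration from YAML
#'
#' Reads the keys of [run_position()] (plus `mesh` / `extra_ids` paths)
#' from a YAML file; unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return named list of arguments for [run_position()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_position)), "posed_surfaces")
  allowed <- c(allowed, "skin_parts", "skeleton_parts", "posed_obj")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}
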