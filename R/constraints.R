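#' Construct a constraint set
#'
#' A constraint set maps node IDs to hard target coordinates, with a tag
#' recording where each entry came from: `"surface"` for posed skin or
#' skeleton surface nodes, `"extra"` for interface nodes whose targets were
#' predicted by local TPS interpolation.
#'
#' @param ids integer vector of external node IDs (unique).
#' @param targets matrix of target coordinates, one row per ID.
#' @param tags character vector (`"surface"` or `"extra"`), recycled.
#' @param source free-form provenance label.
#' @return a `constraint_set`.
#' @export
constraint_set <- function(ids, targets, tags = "surface",
                           source = "manual") {
  ids <- as.integer(ids)
  targets <- as.matrix(targets)
  if (is.null(dim(targets)) || ncol(targets) != 3L ||
      nrow(targets) != length(ids))
    stop("targets must be an m x 3 matrix aligned with ids")
  if (anyDuplicated(ids))
    stop("duplicate constrained node ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!is.finite(targets)))
    stop("non-finite constraint target(s) for node ID(s): ",
         paste(utils::head(ids[rowSums(!is.finite(targets)) > 0L], 5L),
               collapse = ", "))
  tags <- rep_len(as.character(tags), length(ids))
  stopifnot(all(tags %in% c("surface", "extra")))
  dimnames(targets) <- NULL
  structure(list(ids = ids, targets = targets, tags = tags,
                 source = source),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set> ", length(x$ids), " entries (",
      sum(x$tags == "surface"), " surface, ", sum(x$tags == "extra"),
      " extra)\n", sep = "")
  invisible(x)
}

#' Assemble hard constraints from posed boundary surfaces
#'
#' One entry per surface node, tagged `"surface"`. Where surfaces overlap
#' (e.g. a node shared by skin and skeleton extraction), the posed targets
#' must agree to within `tol`; conflicting duplicates are an error naming
#' the offending node IDs.
#'
#' @param mesh the [fe_mesh()] being positioned (targets must reference its
#'   nodes).
#' @param posed_surfaces list of `list(surface = <surface_set>, coords =
#'   <posed matrix aligned with surface$node_ids>)`. The coords may come
#'   from [pose_lbs()] or from a posed OBJ read back with
#'   [read_surface_obj()] via its node-ID sidecar.
#' @param tol agreement tolerance for duplicated nodes. Default `1e-6`.
#' @return a `constraint_set`.
#' @export
assemble_surface_constraints <- function(mesh, posed_surfaces,
                                         tol = 1e-6) {
  ids <- integer(0); tg <- NULL
  for (ps in posed_surfaces) {
    s <- ps$surface; xc <- as.matrix(ps$coords)
    if (nrow(xc) != length(s$node_ids))
      stop("posed coordinates do not align with surface '", s$name, "'")
    ids <- c(ids, s$node_ids)
    tg <- rbind(tg, xc)
  }
  node_index(mesh, ids) # existence check
  dup <- duplicated(ids)
  if (any(dup)) {
    first <- match(ids[dup], ids)
    gap <- sqrt(rowSums((tg[dup, , drop = FALSE] -
                         tg[first, , drop = FALSE])^2))
    bad <- ids[dup][gap > tol]
    if (length(bad))
      stop("conflicting targets for duplicated surface node(s): ",
           paste(utils::head(unique(bad), 5L), collapse = ", "))
  }
  constraint_set(ids[!dup], tg[!dup, , drop = FALSE], tags = "surface",
                 source = paste(vapply(posed_surfaces,
                                       function(p) p$surface$name,
                                       character(1L)), collapse = "+"))
}

#' Predict targets for extra constrained nodes by local TPS interpolation
#'
#' For each candidate node, the k nearest already-constrained nodes (in
#' the *original* coordinates) define a local thin-plate-spline map from
#' their original to their target positions; evaluating it at the
#' candidate's original position yields the candidate's target. Candidates
#' already present in `constraints` are skipped, so the operation is
#' idempotent. Extra constrained nodes placed on component interfaces near
#' joints are what keeps disconnected anatomy (organs, bones) from
#' penetrating its surroundings under large rotations.
#'
#' @param mesh the [fe_mesh()] (original coordinates).
#' @param constraints existing [constraint_set()] (nonempty).
#' @param candidate_ids node IDs to add as `"extra"` constraints.
#' @param k local neighbourhood size (>= 5; default 30).
#' @param ridge TPS regularisation passed to [fit_tps()]. Default 0.
#' @return the input constraints plus the new `"extra"` entries.
#' @export
predict_extra_nodes <- function(mesh, constraints, candidate_ids, k = 30L,
                                ridge = 0) {
  if (k < 5L) stop("k must be at least 5 (affine part has 4 dof in 3-D)")
  if (!length(constraints$ids)) stop("constraints must be nonempty")
  candidate_ids <- setdiff(as.integer(candidate_ids), constraints$ids)
  if (!length(candidate_ids)) return(constraints)

  n_con <- length(constraints$ids)
  if (n_con < k) {
    warning("only ", n_con, " constrained nodes available; using all")
    k <- n_con
  }
  con_src <- mesh$coords[node_index(mesh, constraints$ids), , drop = FALSE]
  cand <- mesh$coords[node_index(mesh, candidate_ids), , drop = FALSE]
  nn <- knn_indices(cand, con_src, k)

  pred <- matrix(NA_real_, length(candidate_ids), 3L)
  for (i in seq_along(candidate_ids)) {
    j <- nn[i, ]
    model <- fit_tps(con_src[j, , drop = FALSE],
                     constraints$targets[j, , drop = FALSE], ridge = ridge)
    pred[i, ] <- predict(model, cand[i, , drop = FALSE])
  }
  if (any(!is.finite(pred)))
    stop("TPS prediction produced non-finite target(s)")
  constraint_set(c(constraints$ids, candidate_ids),
                 rbind(constraints$targets, pred),
                 tags = c(constraints$tags,
                          rep("extra", length(candidate_ids))),
                 source = constraints$source)
}

#' Suggest extra-constraint candidates on a part-pair interface
#'
#' Advisory helper for the manual selection step: returns the nodes of part
#' `part_a` lying within `threshold` of the boundary-surface nodes of part
#' `part_b`, measured in the original mesh. The result is meant to be
#' reviewed (and possibly persisted with [write_id_list()]) before being
#' fed to [predict_extra_nodes()].
#'
#' @param mesh an [fe_mesh()].
#' @param part_a,part_b part IDs (vectors allowed).
#' @param threshold distance threshold (mesh length units); `Inf` returns
#'   every node of `part_a`.
#' @return integer vector of node IDs (possibly empty).
#' @export
select_interface_candidates <- function(mesh, part_a, part_b, threshold) {
  a_ids <- .part_node_ids(mesh, part_a)
  if (!length(a_ids)) return(integer(0))
  if (is.infinite(threshold)) return(sort(a_ids))
  b_surf <- extract_surface(mesh, part_b, name = "b")
  if (!length(b_surf$node_ids)) return(integer(0))
  a_xyz <- mesh$coords[node_index(mesh, a_ids), , drop = FALSE]
  b_xyz <- mesh$coords[node_index(mesh, b_surf$node_ids), , drop = FALSE]
  nn <- knn_indices(a_xyz, b_xyz, 1L)
  d <- sqrt(rowSums((a_xyz - b_xyz[nn[, 1L], , drop = FALSE])^2))
  sort(a_ids[d <= threshold])
}

.part_node_ids <- function(mesh, part_ids) {
  ids <- integer(0)
  for (blk in list(mesh$solids, mesh$shells, mesh$beams)) {
    keep <- blk$pid %in% part_ids
    if (any(keep)) ids <- c(ids, as.vector(blk$conn[keep, , drop = FALSE]))
  }
  sort(unique(ids))
}

#' Read / write constraint sets as JSON
#'
#' Format: `{"constraints": [{"node": id, "target": [x,y,z],
#' "tag": "surface"|"extra"}, ...]}`.
#'
#' @param x a [constraint_set()].
#' @param path file path.
#' @return [read_constraints()] returns a `constraint_set`;
#'   [write_constraints()] returns `path` invisibly.
#' @export
write_constraints <- function(x, path) {
  entries <- lapply(seq_along(x$ids), function(i)
    list(node = x$ids[i], target = as.numeric(x$targets[i, ]),
         tag = x$tags[i]))
  jsonlite::write_json(list(constraints = entries), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)$constraints
  ids <- vapply(raw, function(e) as.integer(e$node), integer(1L))
  targets <- do.call(rbind, lapply(raw, function(e) as.numeric(e$target)))
  tags <- vapply(raw, function(e) e$tag, character(1L))
  constraint_set(ids, targets, tags, source = path)
}

#' Read / write plain-text node-ID lists (one ID per line)
#'
#' Used to persist reviewed extra-constraint candidates for reuse across
#' positioning runs of the same baseline model.
#'
#' @param ids integer vector of node IDs.
#' @param path file path.
#' @return [read_id_list()] returns an integer vector; [write_id_list()]
#'   returns `path` invisibly.
#' @export
write_id_list <- function(ids, path) {
  writeLines(as.character(as.integer(ids)), path)
  invisible(path)
}

#' @rdname write_id_list
#' @export
read_id_list <- function(path) {
  as.integer(readLines(path, warn = FALSE))
}
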