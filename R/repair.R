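#' Plan the repair of distorted elements
#'
#' Elements whose scaled Jacobian falls below `J_threshold` in the
#' positioned mesh are *distorted*. Their nodes are *defective* (they will
#' be moved); the remaining nodes of the distorted elements' neighbouring
#' elements (sharing at least one node) are *reference* nodes, which encode
#' where the neighbourhood ended up. Distorted elements are clustered by
#' node connectivity so each cluster gets its own local fit. Constrained
#' nodes are never moved: if one lands in a distorted element it is
#' reclassified as a reference node (boundary fidelity beats element
#' quality). A cluster whose reference pool has fewer than 5 nodes grows
#' its neighbourhood by up to 3 element rings before being flagged
#' unrepairable.
#'
#' @param positioned_mesh the deformed [fe_mesh()].
#' @param quality a [quality_report()] computed on `positioned_mesh`.
#' @param J_threshold distortion threshold. Default 0.3.
#' @param constrained_ids node IDs that must not move (the hard
#'   constraints), or `NULL`.
#' @return a `repair_plan`: `distorted_eids` (per type), `defective_nodes`,
#'   `reference_nodes`, `clusters` (each with `eids`, `defective`,
#'   `reference`, `repairable`), `J_threshold`.
#' @export
build_repair_plan <- function(positioned_mesh, quality, J_threshold = 0.3,
                              constrained_ids = NULL) {
  mesh <- positioned_mesh
  tab <- quality$table
  elem_conn <- list()
  if (nrow(mesh$solids$conn))
    elem_conn <- c(elem_conn, lapply(seq_len(nrow(mesh$solids$conn)),
      function(r) unique(mesh$solids$conn[r, ])))
  if (nrow(mesh$shells$conn))
    elem_conn <- c(elem_conn, lapply(seq_len(nrow(mesh$shells$conn)),
      function(r) unique(mesh$shells$conn[r, ])))
  if (nrow(tab) != length(elem_conn))
    stop("quality report does not match the mesh")

  distorted <- which(tab$J < J_threshold)
  empty <- structure(list(distorted_idx = integer(0),
                          distorted_eids = tab$eid[integer(0)],
                          defective_nodes = integer(0),
                          reference_nodes = integer(0),
                          clusters = list(), J_threshold = J_threshold),
                     class = "repair_plan")
  if (!length(distorted)) return(empty)

  constrained_ids <- as.integer(constrained_ids)

  # node -> element incidence over all solid/shell elements
  all_nodes <- unlist(elem_conn)
  all_elems <- rep.int(seq_along(elem_conn), lengths(elem_conn))
  node_elems <- split(all_elems, all_nodes) # names are node IDs

  # cluster distorted elements through shared nodes
  d_nodes <- unlist(elem_conn[distorted])
  d_elems <- rep.int(distorted, lengths(elem_conn[distorted]))
  g <- igraph::graph_from_edgelist(
    cbind(paste0("e", d_elems), paste0("n", d_nodes)), directed = FALSE)
  memb <- igraph::components(g)$membership
  e_names <- paste0("e", distorted)
  cluster_of <- memb[e_names]

  defective_all <- integer(0); reference_all <- integer(0)
  clusters <- list()
  for (cl in unique(cluster_of)) {
    eids_local <- distorted[cluster_of == cl]
    cl_nodes <- unique(unlist(elem_conn[eids_local]))
    defective <- setdiff(cl_nodes, constrained_ids)
    frontier <- cl_nodes
    reference <- integer(0)
    for (ring in 1:3) {
      nb_elems <- unique(unlist(node_elems[as.character(frontier)]))
      nb_nodes <- unique(unlist(elem_conn[nb_elems]))
      reference <- setdiff(nb_nodes, defective)
      if (length(reference) >= 5L) break
      frontier <- nb_nodes
    }
    repairable <- length(reference) >= 5L && length(defective) > 0L
    clusters[[length(clusters) + 1L]] <-
      list(eids = tab$eid[eids_local], defective = sort(defective),
           reference = sort(reference), repairable = repairable)
    defective_all <- c(defective_all, defective)
    reference_all <- union(reference_all, reference)
  }
  structure(list(distorted_idx = distorted,
                 distorted_eids = tab$eid[distorted],
                 defective_nodes = sort(unique(defective_all)),
                 reference_nodes = sort(setdiff(reference_all,
                                                defective_all)),
                 clusters = clusters, J_threshold = J_threshold),
            class = "repair_plan")
}

#' @export
print.repair_plan <- function(x, ...) {
  cat("<repair_plan> ", length(x$distorted_eids), " distorted elements, ",
      length(x$clusters), " cluster(s), ", length(x$defective_nodes),
      " defective node(s)\n", sep = "")
  invisible(x)
}

#' Reposition defective nodes by TPS mapping of original relationships
#'
#' Per cluster, a thin-plate spline is fitted from the reference nodes'
#' *original* positions to their *positioned* ones — capturing how the
#' well-conditioned baseline neighbourhood was carried into the target
#' posture — and evaluated at each defective node's original position.
#' Only defective nodes move; everything else is returned bit-identical.
#'
#' @param original_mesh the baseline [fe_mesh()] (well-conditioned).
#' @param positioned_mesh the deformed mesh to be repaired.
#' @param plan a [build_repair_plan()] result.
#' @param ridge TPS regularisation. Default 0.
#' @param max_reference cap on reference nodes per cluster fit; larger
#'   pools are deterministically thinned (dense TPS systems scale as the
#'   cube of the pool). Default 1500.
#' @return list: `coords` (full positioned coordinate matrix), `moved`
#'   (data.frame of node IDs and displacement magnitudes), `skipped`
#'   (cluster indices that could not be repaired).
#' @export
repair_nodes <- function(original_mesh, positioned_mesh, plan, ridge = 0,
                         max_reference = 1500L) {
  coords <- positioned_mesh$coords
  moved_ids <- integer(0); moved_disp <- numeric(0)
  skipped <- integer(0)
  for (ci in seq_along(plan$clusters)) {
    cl <- plan$clusters[[ci]]
    if (!isTRUE(cl$repairable)) { skipped <- c(skipped, ci); next }
    ref <- cl$reference
    if (length(ref) > max_reference)
      ref <- ref[seq(1L, length(ref),
                     length.out = max_reference)]
    src <- original_mesh$coords[node_index(original_mesh, ref), ,
                                drop = FALSE]
    dst <- coords[node_index(positioned_mesh, ref), , drop = FALSE]
    model <- tryCatch(fit_tps(src, dst, ridge = ridge),
                      error = function(e) NULL)
    if (is.null(model)) { skipped <- c(skipped, ci); next }
    di <- node_index(positioned_mesh, cl$defective)
    old <- coords[di, , drop = FALSE]
    new <- predict(model,
                   original_mesh$coords[node_index(original_mesh,
                                                   cl$defective), ,
                                        drop = FALSE])
    if (any(!is.finite(new))) { skipped <- c(skipped, ci); next }
    coords[di, ] <- new
    moved_ids <- c(moved_ids, cl$defective)
    moved_disp <- c(moved_disp, sqrt(rowSums((new - old)^2)))
  }
  list(coords = coords,
       moved = data.frame(node = moved_ids, displacement = moved_disp),
       skipped = skipped)
}

#' Iterate repair until the distorted-element count stops improving
#'
#' Alternates [quality_report()], [build_repair_plan()] and
#' [repair_nodes()] until the count of elements below the J threshold
#' stops strictly decreasing or `max_passes` is reached. A pass that fails
#' to improve the count is discarded, so the returned coordinates are
#' always the best seen and the per-pass count sequence is non-increasing.
#'
#' @inheritParams repair_nodes
#' @param J_threshold distortion threshold. Default 0.3.
#' @param AR_threshold aspect-ratio threshold used for reporting. Default 10.
#' @param max_passes maximum repair passes (>= 1). Default 5.
#' @param constrained_ids immovable node IDs (hard constraints).
#' @return list: `coords` (best coordinates), `passes` (data.frame with
#'   per-pass distortion counts before repair and nodes moved), `report`
#'   (final [quality_report()]).
#' @export
repair_until_stable <- function(original_mesh, positioned_mesh,
                                J_threshold = 0.3, AR_threshold = 10,
                                max_passes = 5L, constrained_ids = NULL,
                                ridge = 0) {
  stopifnot(max_passes >= 1L)
  current <- positioned_mesh
  log <- data.frame(pass = integer(0), n_J_below = integer(0),
                    n_negative_volume = integer(0),
                    n_AR_above = integer(0), nodes_moved = integer(0))
  best_coords <- current$coords
  rep_best <- quality_report(current, J_threshold, AR_threshold)
  best_count <- rep_best$counts$n_J_below
  for (pass in seq_len(max_passes)) {
    rep_now <- quality_report(current, J_threshold, AR_threshold)
    count_now <- rep_now$counts$n_J_below
    if (count_now == 0L) {
      log <- rbind(log, data.frame(pass = pass, n_J_below = 0L,
                                   n_negative_volume = 0L,
                                   n_AR_above = rep_now$counts$n_AR_above,
                                   nodes_moved = 0L))
      best_coords <- current$coords; rep_best <- rep_now
      break
    }
    plan <- build_repair_plan(current, rep_now, J_threshold,
                              constrained_ids)
    res <- repair_nodes(original_mesh, current, plan, ridge = ridge)
    log <- rbind(log, data.frame(
      pass = pass, n_J_below = count_now,
      n_negative_volume = rep_now$counts$n_negative_volume,
      n_AR_above = rep_now$counts$n_AR_above,
      nodes_moved = nrow(res$moved)))
    if (!nrow(res$moved)) break
    candidate <- set_coords(current, res$coords)
    rep_cand <- quality_report(candidate, J_threshold, AR_threshold)
    if (rep_cand$counts$n_J_below < best_count) {
      best_count <- rep_cand$counts$n_J_below
      best_coords <- res$coords
      rep_best <- rep_cand
      current <- candidate
    } else break # no strict improvement: keep best-so-far
  }
  list(coords = best_coords, passes = log, report = rep_best)
}
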