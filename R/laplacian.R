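#' Build the element-connectivity weighted graph of a mesh
#'
#' Two nodes are neighbours if they appear in the same element (solid, shell
#' or beam). Edge weights follow an inverse-cubic law on the node distance
#' in the *original* mesh,
#' \deqn{w_{ij} = 1 / (d_{ij}^3 + \epsilon),}
#' so influence attenuates rapidly with distance; \eqn{\epsilon} guards
#' against division by zero for coincident nodes. The graph Laplacian is
#' \eqn{L = D - A} with \eqn{A} the weighted adjacency matrix and \eqn{D}
#' the diagonal of weighted degrees.
#'
#' @param mesh an [fe_mesh()].
#' @param epsilon small positive constant in the weight denominator, in
#'   (mesh length unit)^3. Default `1e-8`.
#' @return a `laplacian_graph`: `n`, `edges` (m x 2 internal indices,
#'   i < j), `weights`, `degrees`, `L` (sparse symmetric `Matrix`),
#'   `epsilon`, `isolated` (internal indices of nodes in no element,
#'   excluded from the system), and the coordinates the weights were
#'   computed from.
#' @export
build_graph <- function(mesh, epsilon = 1e-8) {
  stopifnot(epsilon > 0)
  n <- length(mesh$node_ids)
  if (!n) stop("mesh has no nodes")

  pair_idx <- function(conn) {
    if (!nrow(conn)) return(NULL)
    k <- ncol(conn)
    combos <- utils::combn(k, 2L)
    i <- conn[, combos[1L, ], drop = FALSE]
    j <- conn[, combos[2L, ], drop = FALSE]
    cbind(as.vector(i), as.vector(j))
  }
  pairs <- rbind(pair_idx(mesh$solids$conn),
                 pair_idx(mesh$shells$conn),
                 pair_idx(mesh$beams$conn))
  if (is.null(pairs) || !nrow(pairs)) stop("mesh has no elements")
  pairs <- matrix(node_index(mesh, pairs), ncol = 2L)
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE] # collapsed
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, 2:1]
  key <- (pairs[, 1L] - 1) * n + pairs[, 2L]
  pairs <- pairs[!duplicated(key), , drop = FALSE]

  d <- sqrt(rowSums((mesh$coords[pairs[, 1L], , drop = FALSE] -
                     mesh$coords[pairs[, 2L], , drop = FALSE])^2))
  if (any(d == 0))
    warning(sum(d == 0), " coincident node pair(s): weight capped at 1/epsilon")
  w <- 1 / (d^3 + epsilon)

  A <- Matrix::sparseMatrix(i = c(pairs[, 1L], pairs[, 2L]),
                            j = c(pairs[, 2L], pairs[, 1L]),
                            x = c(w, w), dims = c(n, n))
  deg <- Matrix::rowSums(A)
  L <- Matrix::Diagonal(n, deg) - A

  isolated <- which(deg == 0)
  if (length(isolated))
    message(length(isolated),
            " isolated node(s) excluded from the Laplacian system")

  structure(list(n = n, edges = pairs, weights = w, degrees = deg, L = L,
                 epsilon = epsilon, isolated = isolated,
                 coords = mesh$coords, node_ids = mesh$node_ids),
            class = "laplacian_graph")
}

#' Differential (Laplacian) coordinates of every node
#'
#' The differential coordinate of node i encodes its position relative to
#' its weighted neighbours, \eqn{\delta_i = \sum_{j \in N(i)} w_{ij}
#' (v_i - v_j)}; in matrix form \eqn{\delta = L V}. These are the local
#' shape descriptors the constrained solve preserves. (The row-normalised
#' variant, dividing row i by \eqn{deg_i}, is a positive rescaling of each
#' equation and yields the same constrained solution; the package works with
#' the unnormalised convention, which keeps L symmetric.)
#'
#' @param graph a [build_graph()] result.
#' @param coords n x 3 coordinate matrix; defaults to the coordinates the
#'   graph was built from.
#' @return n x 3 matrix of differential coordinates; rows of isolated nodes
#'   are `NA`.
#' @export
differential_coordinates <- function(graph, coords = graph$coords) {
  if (nrow(coords) != graph$n) stop("coords do not match the graph")
  delta <- as.matrix(graph$L %*% coords)
  if (length(graph$isolated)) delta[graph$isolated, ] <- NA_real_
  dimnames(delta) <- NULL
  delta
}

#' Partition the Laplacian system into free and constrained nodes
#'
#' Splits the node set into constrained nodes C (positions enforced
#' exactly) and free nodes F (solved for), and extracts the induced blocks
#' \eqn{L_{FF}} and \eqn{L_{FC}} of the constrained linear system
#' \eqn{L_{FF} v_{free} = \delta_{free} - L_{FC} c_{fixed}}. Every
#' connected component of the graph must contain at least one constrained
#' node, otherwise that component's position is undetermined
#' ("unconstrained island") and an error names its parts.
#'
#' @param graph a [build_graph()] result.
#' @param constrained_ids external node IDs to constrain.
#' @param mesh optional [fe_mesh()]; when given, island errors name the
#'   offending part labels.
#' @return a `laplacian_system`: `graph`, `free_idx` / `fixed_idx`
#'   (internal, sorted), `fixed_ids` (external IDs in `fixed_idx` order),
#'   `delta` (precomputed from the original coordinates), `L_FF`, `L_FC`.
#' @export
partition_system <- function(graph, constrained_ids, mesh = NULL) {
  fixed_idx <- sort(match(as.integer(constrained_ids), graph$node_ids))
  if (anyNA(fixed_idx)) stop("constrained ID(s) not in mesh")
  active <- setdiff(seq_len(graph$n), graph$isolated)
  free_idx <- setdiff(active, fixed_idx)

  comp <- .graph_components(graph)
  if (length(free_idx)) {
    anchored <- unique(comp[fixed_idx])
    island <- setdiff(unique(comp[free_idx]), anchored)
    if (length(island)) {
      lab <- .island_labels(graph, mesh, comp, island)
      stop("unconstrained island: component(s) with no constrained node (",
           lab, ")")
    }
  }

  delta <- differential_coordinates(graph)
  list_out <- structure(list(
    graph = graph,
    free_idx = free_idx,
    fixed_idx = fixed_idx,
    fixed_ids = graph$node_ids[fixed_idx],
    delta = delta,
    L_FF = graph$L[free_idx, free_idx, drop = FALSE],
    L_FC = graph$L[free_idx, fixed_idx, drop = FALSE]
  ), class = "laplacian_system")
  list_out
}

# connected components of the element-adjacency graph
.graph_components <- function(graph) {
  g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, graph$n - igraph::vcount(g)))
  igraph::components(g)$membership
}

.island_labels <- function(graph, mesh, comp, island) {
  if (is.null(mesh)) return(paste(length(island), "component(s)"))
  nodes <- graph$node_ids[comp %in% island]
  pids <- integer(0)
  for (blk in list(mesh$solids, mesh$shells, mesh$beams)) {
    if (!nrow(blk$conn)) next
    hit <- matrix(blk$conn %in% nodes, nrow = nrow(blk$conn))
    pids <- c(pids, blk$pid[rowSums(hit) > 0L])
  }
  pids <- sort(unique(pids))
  labs <- as.character(pids)
  if (!is.null(mesh$part_names)) {
    nm <- mesh$part_names[as.character(pids)]
    labs <- ifelse(is.na(nm), labs, paste0(labs, ":", nm))
  }
  paste("parts", paste(labs, collapse = ", "))
}

#' Solve the hard-constrained Laplacian system for free-node positions
#'
#' Solves \eqn{L_{FF} v_{free} = \delta_{free} - L_{FC} c_{fixed}}
#' independently for x, y and z by Jacobi-preconditioned conjugate
#' gradients (\eqn{L_{FF}} is symmetric positive definite once every
#' component is anchored), warm-started from the original free-node
#' positions. On non-convergence the system falls back to a sparse direct
#' factorisation and says so. Constrained nodes are returned bit-equal to
#' their targets; isolated nodes keep their original coordinates.
#'
#' @param system a [partition_system()] result.
#' @param fixed_coords matrix of target coordinates, one row per entry of
#'   `system$fixed_ids` (same order).
#' @param tol relative-residual tolerance for CG. Default `1e-10`.
#' @param max_iter CG iteration cap; default `10 * n_free`.
#' @param method `"cg"` (default) or `"direct"` (sparse Cholesky).
#' @return list: `coords` (full n x 3 matrix), `iterations` (per axis),
#'   `residual` (relative, per axis), `method`.
#' @export
solve_positions <- function(system, fixed_coords, tol = 1e-10,
                            max_iter = NULL, method = c("cg", "direct")) {
  method <- match.arg(method)
  fixed_coords <- as.matrix(fixed_coords)
  if (nrow(fixed_coords) != length(system$fixed_idx))
    stop("fixed_coords must have one row per constrained node")
  graph <- system$graph
  out <- graph$coords # isolated nodes carried through unmoved
  out[system$fixed_idx, ] <- fixed_coords
  nf <- length(system$free_idx)
  # solve in a frame centred on the constraints: the mean target shift is
  # removed before the solve and added back afterwards, so a rigid
  # translation of all targets is reproduced to machine precision instead
  # of solver tolerance
  shift <- colMeans(fixed_coords) -
    colMeans(graph$coords[system$fixed_idx, , drop = FALSE])
  fixed_coords <- sweep(fixed_coords, 2L, shift)
  if (!nf)
    return(list(coords = out, iterations = c(0L, 0L, 0L),
                residual = c(0, 0, 0), method = method))
  if (is.null(max_iter)) max_iter <- 10L * nf

  rhs <- system$delta[system$free_idx, , drop = FALSE] -
    as.matrix(system$L_FC %*% fixed_coords)
  iters <- integer(3L); resid <- numeric(3L)
  if (method == "direct") {
    sol <- as.matrix(Matrix::solve(system$L_FF, rhs))
    for (ax in 1:3) {
      r <- rhs[, ax] - as.numeric(system$L_FF %*% sol[, ax])
      b <- sqrt(sum(rhs[, ax]^2))
      resid[ax] <- if (b > 0) sqrt(sum(r^2)) / b else sqrt(sum(r^2))
    }
    out[system$free_idx, ] <- sweep(sol, 2L, shift, "+")
    return(list(coords = out, iterations = iters, residual = resid,
                method = "direct"))
  }

  dinv <- 1 / Matrix::diag(system$L_FF)
  for (ax in 1:3) {
    cg <- .pcg(system$L_FF, rhs[, ax],
               x0 = graph$coords[system$free_idx, ax],
               dinv = dinv, tol = tol, max_iter = max_iter)
    if (!cg$converged) {
      message("CG did not converge within ", max_iter,
              " iterations; falling back to sparse direct solve")
      sol <- as.matrix(Matrix::solve(system$L_FF, rhs))
      out[system$free_idx, ] <- sweep(sol, 2L, shift, "+")
      return(list(coords = out, iterations = iters, residual = resid,
                  method = "direct"))
    }
    out[system$free_idx, ax] <- cg$x + shift[ax]
    iters[ax] <- cg$iterations
    resid[ax] <- cg$residual
  }
  list(coords = out, iterations = iters, residual = resid, method = "cg")
}

# Jacobi-preconditioned conjugate gradients on an SPD sparse matrix
.pcg <- function(A, b, x0, dinv, tol, max_iter) {
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) bnorm <- 1
  x <- x0
  r <- b - as.numeric(A %*% x)
  rel <- sqrt(sum(r^2)) / bnorm
  if (rel <= tol)
    return(list(x = x, iterations = 0L, residual = rel, converged = TRUE))
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / bnorm
    if (rel <= tol)
      return(list(x = x, iterations = it, residual = rel, converged = TRUE))
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = max_iter, residual = rel, converged = FALSE)
}
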