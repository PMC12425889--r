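#' Scaled Jacobian of a single element
#'
#' The scaled (normalised) corner Jacobian: at each corner, the determinant
#' of the three (two, for shells) emanating edge vectors, each normalised
#' to unit length; the element value is the minimum over corners. A perfect
#' cube / square scores 1, an inverted ("negative volume") element scores
#' below 0, and for hexahedra the value lies in [-1, 1]. Tetrahedra use the
#' corner frame at node 1 divided by \eqn{\sqrt{2}/2} so the regular
#' tetrahedron scores 1; triangles divide by \eqn{\sqrt{3}/2} so the
#' equilateral triangle scores 1.
#'
#' @param verts k x 3 matrix of corner coordinates in element order
#'   (hex8, tet4, quad4 or tri3).
#' @param type `"hex"`, `"tet"`, `"quad"` or `"tri"`.
#' @return scalar J; 0 with a `"degenerate"` attribute if a corner frame
#'   has a zero-length edge at every corner.
#' @export
scaled_jacobian <- function(verts,
                            type = c("hex", "tet", "quad", "tri")) {
  type <- match.arg(type)
  verts <- as.matrix(verts)
  conn <- matrix(seq_len(nrow(verts)), nrow = 1L)
  J <- switch(type,
    hex = .hex_jacobian(conn, verts),
    tet = .tet_jacobian(conn, verts),
    quad = .quad_jacobian(conn, verts),
    tri = .tri_jacobian(conn[, 1:3, drop = FALSE], verts))
  J$J[1L]
}

# corner c of a hex and its three edge-adjacent corners, oriented so a
# right-handed hex gives positive determinants
.hex_corners <- rbind(c(1L, 2L, 4L, 5L), c(2L, 3L, 1L, 6L),
                      c(3L, 4L, 2L, 7L), c(4L, 1L, 3L, 8L),
                      c(5L, 8L, 6L, 1L), c(6L, 5L, 7L, 2L),
                      c(7L, 6L, 8L, 3L), c(8L, 7L, 5L, 4L))

.row_det3 <- function(a, b, c) {
  a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
  a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
  a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
}

.row_norm <- function(x) sqrt(rowSums(x^2))

.row_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# conn: m x 8 internal row indices into coords
.hex_jacobian <- function(conn, coords) {
  m <- nrow(conn)
  Jc <- matrix(NA_real_, m, 8L)
  for (c in seq_len(8L)) {
    ci <- .hex_corners[c, ]
    vc <- coords[conn[, ci[1L]], , drop = FALSE]
    e1 <- coords[conn[, ci[2L]], , drop = FALSE] - vc
    e2 <- coords[conn[, ci[3L]], , drop = FALSE] - vc
    e3 <- coords[conn[, ci[4L]], , drop = FALSE] - vc
    l1 <- .row_norm(e1); l2 <- .row_norm(e2); l3 <- .row_norm(e3)
    ok <- l1 > 0 & l2 > 0 & l3 > 0
    val <- .row_det3(e1, e2, e3) / (l1 * l2 * l3)
    Jc[, c] <- ifelse(ok, val, NA_real_)
  }
  all_na <- rowSums(!is.na(Jc)) == 0L
  J <- suppressWarnings(apply(Jc, 1L, min, na.rm = TRUE))
  J[all_na] <- 0
  list(J = J, degenerate = all_na)
}

.tet_jacobian <- function(conn, coords) {
  m <- nrow(conn)
  J <- numeric(m); degen <- logical(m)
  for (r in seq_len(m)) {
    u <- unique(conn[r, ])
    v <- coords[u, , drop = FALSE]
    e <- sweep(v[2:4, , drop = FALSE], 2L, v[1L, ])
    l <- sqrt(rowSums(e^2))
    if (any(l == 0)) { degen[r] <- TRUE; next }
    J[r] <- det(t(e)) / prod(l) / (sqrt(2) / 2)
  }
  list(J = J, degenerate = degen)
}

.quad_corners <- rbind(c(1L, 2L, 4L), c(2L, 3L, 1L),
                       c(3L, 4L, 2L), c(4L, 1L, 3L))

.quad_jacobian <- function(conn, coords) {
  m <- nrow(conn)
  d1 <- coords[conn[, 3L], , drop = FALSE] - coords[conn[, 1L], , drop = FALSE]
  d2 <- coords[conn[, 4L], , drop = FALSE] - coords[conn[, 2L], , drop = FALSE]
  nrm <- .row_cross(d1, d2)
  nlen <- .row_norm(nrm)
  nrm <- nrm / ifelse(nlen > 0, nlen, 1)
  Jc <- matrix(NA_real_, m, 4L)
  for (c in seq_len(4L)) {
    ci <- .quad_corners[c, ]
    vc <- coords[conn[, ci[1L]], , drop = FALSE]
    e1 <- coords[conn[, ci[2L]], , drop = FALSE] - vc
    e2 <- coords[conn[, ci[3L]], , drop = FALSE] - vc
    l1 <- .row_norm(e1); l2 <- .row_norm(e2)
    ok <- l1 > 0 & l2 > 0 & nlen > 0
    val <- rowSums(.row_cross(e1, e2) * nrm) / (l1 * l2)
    Jc[, c] <- ifelse(ok, val, NA_real_)
  }
  all_na <- rowSums(!is.na(Jc)) == 0L
  J <- suppressWarnings(apply(Jc, 1L, min, na.rm = TRUE))
  J[all_na] <- 0
  list(J = J, degenerate = all_na)
}

.tri_jacobian <- function(conn, coords) {
  m <- nrow(conn)
  e1g <- coords[conn[, 2L], , drop = FALSE] - coords[conn[, 1L], , drop = FALSE]
  e2g <- coords[conn[, 3L], , drop = FALSE] - coords[conn[, 1L], , drop = FALSE]
  nrm <- .row_cross(e1g, e2g)
  nlen <- .row_norm(nrm)
  nrm <- nrm / ifelse(nlen > 0, nlen, 1)
  corners <- rbind(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  Jc <- matrix(NA_real_, m, 3L)
  for (c in seq_len(3L)) {
    ci <- corners[c, ]
    vc <- coords[conn[, ci[1L]], , drop = FALSE]
    e1 <- coords[conn[, ci[2L]], , drop = FALSE] - vc
    e2 <- coords[conn[, ci[3L]], , drop = FALSE] - vc
    l1 <- .row_norm(e1); l2 <- .row_norm(e2)
    ok <- l1 > 0 & l2 > 0 & nlen > 0
    val <- rowSums(.row_cross(e1, e2) * nrm) / (l1 * l2) / (sqrt(3) / 2)
    Jc[, c] <- ifelse(ok, val, NA_real_)
  }
  all_na <- rowSums(!is.na(Jc)) == 0L
  J <- suppressWarnings(apply(Jc, 1L, min, na.rm = TRUE))
  J[all_na] <- 0
  list(J = J, degenerate = all_na)
}

#' Aspect ratio of a single element
#'
#' Longest edge length divided by shortest edge length over the element's
#' edge set (12 edges for a hex, 6 for a tet, 4 for a quad, 3 for a
#' triangle). Edges collapsed *structurally* (the same node repeated in the
#' connectivity, as in degenerate hex records) are excluded; a
#' geometrically zero-length edge between distinct nodes yields `Inf`.
#'
#' @inheritParams scaled_jacobian
#' @return scalar AR >= 1 (or `Inf`).
#' @export
aspect_ratio <- function(verts, type = c("hex", "tet", "quad", "tri")) {
  type <- match.arg(type)
  verts <- as.matrix(verts)
  conn <- matrix(seq_len(nrow(verts)), nrow = 1L)
  edges <- switch(type,
    hex = .hex_edges, tet = utils::combn(4L, 2L), quad = .quad_edges,
    tri = rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L)))
  if (type == "tet") edges <- t(edges)
  .edge_aspect(conn, verts, edges)[1L]
}

.hex_edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L),
                    c(5L, 6L), c(6L, 7L), c(7L, 8L), c(8L, 5L),
                    c(1L, 5L), c(2L, 6L), c(3L, 7L), c(4L, 8L))
.quad_edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L))

# conn rows index coords; ids (same shape) give external IDs for detecting
# structural collapse -- when absent, conn itself serves
.edge_aspect <- function(conn, coords, edges, ids = conn) {
  m <- nrow(conn)
  lens <- matrix(NA_real_, m, nrow(edges))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    l <- .row_norm(coords[conn[, a], , drop = FALSE] -
                   coords[conn[, b], , drop = FALSE])
    l[ids[, a] == ids[, b]] <- NA_real_ # structural collapse: not an edge
    lens[, e] <- l
  }
  mx <- suppressWarnings(apply(lens, 1L, max, na.rm = TRUE))
  mn <- suppressWarnings(apply(lens, 1L, min, na.rm = TRUE))
  ar <- ifelse(mn > 0, mx / mn, Inf)
  ar[!is.finite(mx)] <- Inf # no surviving edges at all
  ar
}

#' Mesh-wide quality report with the three distortion counts
#'
#' Evaluates the scaled Jacobian and aspect ratio of every solid and shell
#' element (1-D elements carry no meaningful shape metric and are
#' excluded), and tallies the three standard distortion counts: elements
#' with J below `J_threshold`, inverted elements (J < 0, negative volume),
#' and elements with aspect ratio above `AR_threshold`.
#'
#' @param mesh an [fe_mesh()].
#' @param J_threshold distorted-element threshold on J. Default 0.3.
#' @param AR_threshold stretching threshold on AR. Default 10.
#' @return a `quality_report`: `table` (data.frame with `eid`, `type`,
#'   `pid`, `J`, `AR`, `degenerate`), `counts` (named list `n_J_below`,
#'   `n_negative_volume`, `n_AR_above`), `thresholds`.
#' @export
quality_report <- function(mesh, J_threshold = 0.3, AR_threshold = 10) {
  idx <- function(ids) {
    m <- node_index(mesh, ids)
    dim(m) <- dim(ids)
    m
  }
  rows <- list()
  if (nrow(mesh$solids$conn)) {
    conn <- idx(mesh$solids$conn)
    distinct <- .solid_distinct_counts(mesh$solids$conn)
    is_tet <- distinct == 4L
    J <- numeric(nrow(conn)); degen <- logical(nrow(conn))
    if (any(!is_tet)) {
      h <- .hex_jacobian(conn[!is_tet, , drop = FALSE], mesh$coords)
      J[!is_tet] <- h$J; degen[!is_tet] <- h$degenerate
    }
    if (any(is_tet)) {
      t4 <- .tet_jacobian(conn[is_tet, , drop = FALSE], mesh$coords)
      J[is_tet] <- t4$J; degen[is_tet] <- t4$degenerate
    }
    AR <- .edge_aspect(conn, mesh$coords, .hex_edges,
                       ids = mesh$solids$conn)
    rows[[1L]] <- data.frame(eid = mesh$solids$eid, type = "solid",
                             pid = mesh$solids$pid, J = J, AR = AR,
                             degenerate = degen)
  }
  if (nrow(mesh$shells$conn)) {
    conn <- idx(mesh$shells$conn)
    is_tri <- mesh$shells$conn[, 3L] == mesh$shells$conn[, 4L]
    J <- numeric(nrow(conn)); degen <- logical(nrow(conn))
    if (any(!is_tri)) {
      q <- .quad_jacobian(conn[!is_tri, , drop = FALSE], mesh$coords)
      J[!is_tri] <- q$J; degen[!is_tri] <- q$degenerate
    }
    if (any(is_tri)) {
      t3 <- .tri_jacobian(conn[is_tri, 1:3, drop = FALSE], mesh$coords)
      J[is_tri] <- t3$J; degen[is_tri] <- t3$degenerate
    }
    AR <- .edge_aspect(conn, mesh$coords, .quad_edges,
                       ids = mesh$shells$conn)
    rows[[2L]] <- data.frame(eid = mesh$shells$eid, type = "shell",
                             pid = mesh$shells$pid, J = J, AR = AR,
                             degenerate = degen)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(eid = integer(0), type = character(0),
                      pid = integer(0), J = numeric(0), AR = numeric(0),
                      degenerate = logical(0))
  structure(list(
    table = tab,
    counts = list(n_J_below = sum(tab$J < J_threshold),
                  n_negative_volume = sum(tab$J < 0),
                  n_AR_above = sum(tab$AR > AR_threshold)),
    thresholds = list(J = J_threshold, AR = AR_threshold)
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report> ", nrow(x$table), " elements\n", sep = "")
  cat(sprintf("  J < %-4s : %d\n", format(x$thresholds$J),
              x$counts$n_J_below))
  cat(sprintf("  J < 0    : %d (negative volume)\n",
              x$counts$n_negative_volume))
  cat(sprintf("  AR > %-3s : %d\n", format(x$thresholds$AR),
              x$counts$n_AR_above))
  invisible(x)
}

#' Write the per-element quality table as CSV
#' @param report a [quality_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quality_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
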