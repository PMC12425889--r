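#' Volumetric finite-element mesh container
#'
#' An `fe_mesh` holds the node table and typed element blocks of a volumetric
#' finite-element model: 8-node hexahedra / 4-node tetrahedra (solids, with
#' tetrahedra optionally encoded as collapsed hex records), 4-node
#' quadrilaterals / 3-node triangles (shells, triangles encoded with the
#' fourth node repeating the third), and 2-node beams. Elements carry the
#' part (component) they belong to, e.g. skin, flesh, bone.
#'
#' External node IDs are positive integers and need not be contiguous;
#' internally the package works with 0-free, 1-based row indices into
#' `coords` and converts via [node_index()].
#'
#' @param node_ids integer vector of unique positive external node IDs.
#' @param coords numeric matrix, one row per node, three columns (x, y, z).
#'   Length units are the caller's (mm by convention).
#' @param solids,shells,beams element blocks: a list with integer matrix
#'   `conn` (connectivity by external node ID; 8 / 4 / 2 columns), integer
#'   `eid` (element IDs) and integer `pid` (part IDs). `NULL` for none.
#' @param part_names named character vector mapping part ID to a label, or
#'   `NULL`.
#' @return object of class `fe_mesh`.
#' @export
fe_mesh <- function(node_ids, coords, solids = NULL, shells = NULL,
                    beams = NULL, part_names = NULL) {
  node_ids <- as.integer(node_ids)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L || nrow(coords) != length(node_ids))
    stop("coords must be an n x 3 matrix aligned with node_ids")
  dup <- node_ids[duplicated(node_ids)]
  if (length(dup))
    stop("duplicate node ID(s): ", paste(unique(dup), collapse = ", "))
  if (any(node_ids <= 0L)) stop("node IDs must be positive")
  dimnames(coords) <- NULL

  mesh <- structure(list(
    node_ids = node_ids,
    coords = coords,
    solids = .check_block(solids, 8L, node_ids, "solid"),
    shells = .check_block(shells, 4L, node_ids, "shell"),
    beams  = .check_block(beams, 2L, node_ids, "beam"),
    part_names = part_names
  ), class = "fe_mesh")
  mesh
}

.empty_block <- function(width) {
  list(conn = matrix(integer(0), 0L, width), eid = integer(0),
       pid = integer(0))
}

.check_block <- function(block, width, node_ids, what) {
  if (is.null(block)) return(.empty_block(width))
  conn <- block$conn
  if (is.null(dim(conn))) conn <- matrix(as.integer(conn), ncol = width,
                                         byrow = TRUE)
  storage.mode(conn) <- "integer"
  if (ncol(conn) != width)
    stop(what, " connectivity must have ", width, " columns")
  missing <- setdiff(unique(as.vector(conn)), node_ids)
  if (length(missing))
    stop(what, " element references missing node ID(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  eid <- as.integer(block$eid %||% seq_len(nrow(conn)))
  pid <- as.integer(block$pid %||% rep(1L, nrow(conn)))
  if (length(eid) != nrow(conn) || length(pid) != nrow(conn))
    stop(what, " eid/pid lengths do not match connectivity")
  dimnames(conn) <- NULL
  list(conn = conn, eid = eid, pid = pid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map external node IDs to internal row indices
#'
#' @param mesh an [fe_mesh()].
#' @param ids integer vector (or matrix) of external node IDs.
#' @return integer object of the same shape with row indices into
#'   `mesh$coords`; unknown IDs raise an error.
#' @export
node_index <- function(mesh, ids) {
  idx <- match(as.vector(ids), mesh$node_ids)
  if (anyNA(idx))
    stop("unknown node ID(s): ",
         paste(utils::head(as.vector(ids)[is.na(idx)], 5L), collapse = ", "))
  if (is.matrix(ids)) dim(idx) <- dim(ids)
  idx
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat("<fe_mesh> ", length(x$node_ids), " nodes | ",
      nrow(x$solids$conn), " solids, ", nrow(x$shells$conn), " shells, ",
      nrow(x$beams$conn), " beams | parts: ",
      paste(sort(unique(c(x$solids$pid, x$shells$pid, x$beams$pid))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Bounding-box diagonal of a mesh or coordinate matrix
#' @param x an `fe_mesh` or an n x 3 coordinate matrix.
#' @return scalar length of the axis-aligned bounding-box diagonal.
#' @export
bbox_diagonal <- function(x) {
  coords <- if (inherits(x, "fe_mesh")) x$coords else x
  sqrt(sum((apply(coords, 2L, max) - apply(coords, 2L, min))^2))
}

#' Part IDs present in a mesh
#' @param mesh an [fe_mesh()].
#' @return sorted integer vector of part IDs over all element types.
#' @export
mesh_parts <- function(mesh) {
  sort(unique(c(mesh$solids$pid, mesh$shells$pid, mesh$beams$pid)))
}

# number of distinct nodes per solid record (4 => tet encoded as hex, 8 => hex)
.solid_distinct_counts <- function(conn) {
  apply(conn, 1L, function(r) length(unique(r)))
}

#' Replace the node coordinates of a mesh
#' @param mesh an [fe_mesh()].
#' @param coords replacement n x 3 matrix aligned with `mesh$node_ids`.
#' @return the mesh with new coordinates.
#' @export
set_coords <- function(mesh, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(mesh$node_ids) || ncol(coords) != 3L)
    stop("coords must match the mesh node table")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  mesh$coords <- coords
  mesh
}
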