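#' Extract the boundary surface of a part group
#'
#' Boundary faces of a set of parts: solid-element faces referenced exactly
#' once within the part group (faces shared by two solids are interior),
#' plus every shell element of parts that contain only shells. Face identity
#' is the sorted node-ID tuple, so extraction is independent of element
#' ordering and orientation.
#'
#' @param mesh an [fe_mesh()].
#' @param part_ids integer vector of part IDs forming the group.
#' @param name label for the surface (e.g. `"skin"`, `"skeleton"`).
#' @return a `surface_set`: list with `name`, `node_ids` (external IDs
#'   appearing in the faces) and `faces` (integer matrix, one row per face,
#'   4 columns; triangles repeat the third node in the fourth slot).
#' @export
extract_surface <- function(mesh, part_ids, name = "surface") {
  part_ids <- as.integer(part_ids)
  if (!length(part_ids)) stop("part_ids must be nonempty")
  known <- mesh_parts(mesh)
  bad <- setdiff(part_ids, known)
  if (length(bad))
    stop("unknown part ID(s): ", paste(bad, collapse = ", "))

  faces <- matrix(integer(0), 0L, 4L)

  sol <- mesh$solids$pid %in% part_ids
  if (any(sol)) {
    conn <- mesh$solids$conn[sol, , drop = FALSE]
    faces <- rbind(faces, .boundary_faces_solids(conn))
  }
  # parts represented only by shells contribute their shells as faces
  for (pid in part_ids) {
    has_solid <- any(mesh$solids$pid == pid)
    sh <- mesh$shells$pid == pid
    if (!has_solid && any(sh))
      faces <- rbind(faces, mesh$shells$conn[sh, , drop = FALSE])
  }
  structure(list(name = name,
                 node_ids = sort(unique(as.vector(faces))),
                 faces = faces),
            class = "surface_set")
}

# all faces of a block of solid records; returns those referenced once
.boundary_faces_solids <- function(conn) {
  distinct <- .solid_distinct_counts(conn)
  faces <- list()
  hex_face_idx <- rbind(c(1L, 2L, 3L, 4L), c(5L, 8L, 7L, 6L),
                        c(1L, 5L, 6L, 2L), c(2L, 6L, 7L, 3L),
                        c(3L, 7L, 8L, 4L), c(4L, 8L, 5L, 1L))
  hex <- which(distinct >= 5L) # hexes incl. partially collapsed wedges
  if (length(hex)) {
    for (f in seq_len(6L)) {
      faces[[length(faces) + 1L]] <-
        conn[hex, hex_face_idx[f, ], drop = FALSE]
    }
  }
  tet <- which(distinct == 4L)
  if (length(tet)) {
    tconn <- t(apply(conn[tet, , drop = FALSE], 1L,
                     function(r) unique(r)))
    tet_face_idx <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L),
                          c(1L, 3L, 4L), c(2L, 3L, 4L))
    for (f in seq_len(4L)) {
      tf <- tconn[, tet_face_idx[f, ], drop = FALSE]
      faces[[length(faces) + 1L]] <- cbind(tf, tf[, 3L])
    }
  }
  faces <- do.call(rbind, faces)
  if (is.null(faces)) return(matrix(integer(0), 0L, 4L))
  # drop collapsed faces (fewer than 3 distinct corners)
  ndist <- apply(faces, 1L, function(r) length(unique(r)))
  faces <- faces[ndist >= 3L, , drop = FALSE]
  key <- apply(faces, 1L, function(r)
    paste(sort(unique(r)), collapse = "_"))
  once <- names(which(table(key) == 1L))
  faces[key %in% once, , drop = FALSE]
}

#' @export
print.surface_set <- function(x, ...) {
  cat("<surface_set '", x$name, "'> ", length(x$node_ids), " nodes, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

#' Export a surface to a Wavefront OBJ file with an index sidecar
#'
#' Vertices are written in `surface$node_ids` order. Because OBJ files index
#' vertices 1..V with no room for external IDs, a JSON sidecar
#' (`<path>.map.json`) stores the OBJ-vertex-to-node-ID map so posed OBJ
#' vertices can be mapped back onto mesh constraints.
#'
#' @param surface a `surface_set` from [extract_surface()].
#' @param mesh the [fe_mesh()] providing coordinates.
#' @param path output `.obj` path.
#' @return `path`, invisibly.
#' @export
export_surface_obj <- function(surface, mesh, path) {
  bad <- setdiff(unique(as.vector(surface$faces)), surface$node_ids)
  if (length(bad))
    stop("face references node outside the surface: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  v <- mesh$coords[node_index(mesh, surface$node_ids), , drop = FALSE]
  vert_of <- match(surface$faces, surface$node_ids)
  dim(vert_of) <- dim(surface$faces)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  tri <- vert_of[, 3L] == vert_of[, 4L]
  if (any(tri))
    writeLines(sprintf("f %d %d %d", vert_of[tri, 1L], vert_of[tri, 2L],
                       vert_of[tri, 3L]), con)
  if (any(!tri))
    writeLines(sprintf("f %d %d %d %d", vert_of[!tri, 1L],
                       vert_of[!tri, 2L], vert_of[!tri, 3L],
                       vert_of[!tri, 4L]), con)
  jsonlite::write_json(list(node_ids = surface$node_ids),
                       paste0(path, ".map.json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read vertices (and faces) back from an OBJ file
#'
#' @param path `.obj` path. If the `<path>.map.json` sidecar written by
#'   [export_surface_obj()] exists, vertex rows are labelled with external
#'   node IDs.
#' @return list with `coords` (V x 3), `faces` (rows of vertex indices,
#'   4-column, triangles repeating the third), and `node_ids` (or `NULL`).
#' @export
read_surface_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  coords <- do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(t)
    as.numeric(t[2:4])))
  faces <- NULL
  if (length(fl)) {
    faces <- do.call(rbind, lapply(strsplit(fl, "[[:space:]]+"), function(t) {
      idx <- as.integer(sub("/.*", "", t[-1L]))
      if (length(idx) == 3L) idx <- c(idx, idx[3L])
      idx[1:4]
    }))
  }
  side <- paste0(path, ".map.json")
  node_ids <- NULL
  if (file.exists(side))
    node_ids <- as.integer(jsonlite::read_json(side,
                                               simplifyVector = TRUE)$node_ids)
  list(coords = coords, faces = faces, node_ids = node_ids)
}

#' Write a mesh as a legacy VTK unstructured grid (inspection only)
#'
#' @param mesh an [fe_mesh()].
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- length(mesh$node_ids)
  idx_of <- function(ids) node_index(mesh, ids) - 1L
  writeLines(c("# vtk DataFile Version 3.0", "fe_mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$coords[, 1L],
                     mesh$coords[, 2L], mesh$coords[, 3L]), con)
  cells <- character(0); types <- integer(0)
  if (nrow(mesh$solids$conn)) {
    distinct <- .solid_distinct_counts(mesh$solids$conn)
    for (r in seq_len(nrow(mesh$solids$conn))) {
      row <- mesh$solids$conn[r, ]
      if (distinct[r] == 4L) {
        u <- unique(row)
        cells <- c(cells, paste(c(4L, idx_of(u)), collapse = " "))
        types <- c(types, 10L) # VTK_TETRA
      } else {
        cells <- c(cells, paste(c(8L, idx_of(row)), collapse = " "))
        types <- c(types, 12L) # VTK_HEXAHEDRON
      }
    }
  }
  if (nrow(mesh$shells$conn)) {
    for (r in seq_len(nrow(mesh$shells$conn))) {
      row <- mesh$shells$conn[r, ]
      if (row[3L] == row[4L]) {
        cells <- c(cells, paste(c(3L, idx_of(row[1:3])), collapse = " "))
        types <- c(types, 5L) # VTK_TRIANGLE
      } else {
        cells <- c(cells, paste(c(4L, idx_of(row)), collapse = " "))
        types <- c(types, 9L) # VTK_QUAD
      }
    }
  }
  if (nrow(mesh$beams$conn)) {
    for (r in seq_len(nrow(mesh$beams$conn))) {
      cells <- c(cells, paste(c(2L, idx_of(mesh$beams$conn[r, ])),
                              collapse = " "))
      types <- c(types, 3L) # VTK_LINE
    }
  }
  sizes <- vapply(strsplit(cells, " "), length, integer(1L))
  writeLines(sprintf("CELLS %d %d", length(cells), sum(sizes)), con)
  writeLines(cells, con)
  writeLines(sprintf("CELL_TYPES %d", length(types)), con)
  writeLines(as.character(types), con)
  invisible(path)
}
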