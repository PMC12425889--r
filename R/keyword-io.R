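#' Read a volumetric mesh from an LS-DYNA-style keyword file
#'
#' Parses the keyword subset `*NODE`, `*ELEMENT_SOLID`, `*ELEMENT_SHELL`,
#' `*ELEMENT_BEAM`, `*PART` and `*END`. Both the fixed-width card layout
#' (8-character integer fields, 16-character coordinate fields) and the
#' comma-separated dialect are accepted; the two may be mixed line by line.
#' Comment lines (`$`) are ignored. Unknown keyword blocks (materials,
#' sections, contacts, ...) are skipped with a single warning naming them.
#'
#' @param path path to the keyword text file.
#' @return an [fe_mesh()].
#' @export
read_keyword_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines, "left"), "$")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty keyword file: ", path)

  is_kw <- startsWith(lines, "*")
  if (!any(is_kw)) stop("no keyword cards found in ", path)
  kw_pos <- which(is_kw)
  kw_name <- toupper(trimws(lines[kw_pos]))

  node_rows <- list(); solid_rows <- list(); shell_rows <- list()
  beam_rows <- list(); part_ids <- integer(0); part_titles <- character(0)
  skipped <- character(0)

  for (b in seq_along(kw_pos)) {
    from <- kw_pos[b] + 1L
    to <- if (b < length(kw_pos)) kw_pos[b + 1L] - 1L else length(lines)
    if (from > to) body <- character(0) else body <- lines[from:to]
    kw <- kw_name[b]
    if (kw == "*END") break
    if (kw == "*NODE") {
      node_rows[[length(node_rows) + 1L]] <-
        .parse_cards(body, n_fields = 4L, widths = c(8L, 16L, 16L, 16L))
    } else if (startsWith(kw, "*ELEMENT_SOLID")) {
      solid_rows[[length(solid_rows) + 1L]] <-
        .parse_cards(body, n_fields = 10L, widths = rep(8L, 10L),
                     min_fields = 6L)
    } else if (startsWith(kw, "*ELEMENT_SHELL")) {
      shell_rows[[length(shell_rows) + 1L]] <-
        .parse_cards(body, n_fields = 6L, widths = rep(8L, 6L),
                     min_fields = 5L)
    } else if (startsWith(kw, "*ELEMENT_BEAM")) {
      beam_rows[[length(beam_rows) + 1L]] <-
        .parse_cards(body, n_fields = 4L, widths = rep(8L, 4L),
                     min_fields = 4L)
    } else if (startsWith(kw, "*PART")) {
      pp <- .parse_part(body)
      part_ids <- c(part_ids, pp$pid)
      part_titles <- c(part_titles, pp$title)
    } else if (kw != "*KEYWORD") {
      skipped <- c(skipped, kw)
    }
  }
  if (length(skipped))
    warning("skipped unknown keyword block(s): ",
            paste(unique(skipped), collapse = ", "))

  nodes <- do.call(rbind, node_rows)
  if (is.null(nodes) || !nrow(nodes)) stop("no *NODE block in ", path)
  ids <- as.integer(nodes[, 1L])
  if (anyDuplicated(ids))
    stop("duplicate node ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  part_names <- NULL
  if (length(part_ids)) {
    part_names <- part_titles
    names(part_names) <- as.character(part_ids)
  }

  .block_from <- function(rows, conn_cols) {
    m <- do.call(rbind, rows)
    if (is.null(m) || !nrow(m)) return(NULL)
    list(conn = matrix(as.integer(m[, conn_cols, drop = FALSE]),
                       nrow = nrow(m)),
         eid = as.integer(m[, 1L]), pid = as.integer(m[, 2L]))
  }

  # tets commonly arrive padded: n1 n2 n3 n4 n4 n4 n4 n4 (or zero-padded)
  solids <- .block_from(solid_rows, 3:10)
  if (!is.null(solids)) {
    zero <- solids$conn == 0L
    if (any(zero)) { # zero padding: repeat node 4 into trailing slots
      for (r in which(rowSums(zero) > 0L)) {
        row <- solids$conn[r, ]
        row[row == 0L] <- row[max(which(row != 0L))]
        solids$conn[r, ] <- row
      }
    }
  }
  shells <- .block_from(shell_rows, 3:6)
  if (!is.null(shells)) { # triangle padded with 0 -> repeat third node
    zero <- shells$conn[, 4L] == 0L
    shells$conn[zero, 4L] <- shells$conn[zero, 3L]
  }
  beams <- .block_from(beam_rows, 3:4)

  fe_mesh(ids, nodes[, 2:4, drop = FALSE], solids = solids, shells = shells,
          beams = beams, part_names = part_names)
}

# Parse card lines into a numeric matrix. Comma lines are split on commas;
# other lines are whitespace-split when that yields enough tokens, else cut
# at the fixed widths (packed decks with no separating blanks).
.parse_cards <- function(body, n_fields, widths, min_fields = n_fields) {
  if (!length(body)) return(NULL)
  out <- matrix(0, nrow = length(body), ncol = n_fields)
  comma <- grepl(",", body, fixed = TRUE)
  fill_row <- function(vals) {
    vals <- suppressWarnings(as.numeric(vals))
    length(vals) <- n_fields
    vals[is.na(vals)] <- 0
    vals
  }
  if (any(comma)) {
    toks <- strsplit(body[comma], ",", fixed = TRUE)
    out[comma, ] <- t(vapply(toks, fill_row, numeric(n_fields)))
  }
  if (any(!comma)) {
    plain <- body[!comma]
    toks <- strsplit(trimws(plain), "[[:space:]]+")
    ok <- lengths(toks) >= min_fields
    if (any(ok)) {
      rows <- which(!comma)[ok]
      out[rows, ] <- t(vapply(toks[ok], fill_row, numeric(n_fields)))
    }
    if (any(!ok)) { # fixed-width fallback
      starts <- cumsum(c(1L, widths[-length(widths)]))
      ends <- cumsum(widths)
      rows <- which(!comma)[!ok]
      for (i in seq_along(rows)) {
        ln <- plain[!ok][i]
        out[rows[i], ] <- fill_row(substring(ln, starts, ends))
      }
    }
  }
  out
}

.parse_part <- function(body) {
  if (!length(body)) return(list(pid = integer(0), title = character(0)))
  title <- trimws(body[1L])
  pid <- NA_integer_
  if (length(body) >= 2L) {
    toks <- strsplit(trimws(body[2L]), "[,[:space:]]+")[[1L]]
    pid <- suppressWarnings(as.integer(toks[1L]))
  }
  if (is.na(pid)) { # single-line *PART without a heading card
    toks <- strsplit(trimws(body[1L]), "[,[:space:]]+")[[1L]]
    pid <- suppressWarnings(as.integer(toks[1L]))
    title <- paste0("part_", pid)
  }
  list(pid = pid, title = title)
}

#' Write a mesh to an LS-DYNA-style keyword file
#'
#' Emits `*PART`, `*NODE`, `*ELEMENT_SOLID`, `*ELEMENT_SHELL` and
#' `*ELEMENT_BEAM` blocks in the fixed-width card layout, preserving
#' external node IDs, element IDs, part IDs and corner ordering verbatim
#' (degenerate/collapsed records included). Coordinates are written with 9
#' significant digits so a read/write round trip preserves them to better
#' than 1e-7 relative error.
#'
#' @param mesh an [fe_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_keyword_mesh <- function(mesh, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("*KEYWORD")
  if (!is.null(mesh$part_names)) {
    for (pid in names(mesh$part_names)) {
      wl("*PART", mesh$part_names[[pid]], sprintf("%10d", as.integer(pid)))
    }
  }
  wl("*NODE")
  wl(sprintf("%8d%16.8e%16.8e%16.8e", mesh$node_ids,
             mesh$coords[, 1L], mesh$coords[, 2L], mesh$coords[, 3L]))
  .write_elem <- function(kw, block) {
    if (!nrow(block$conn)) return()
    wl(kw)
    fields <- cbind(block$eid, block$pid, block$conn)
    fmt <- paste(rep("%8d", ncol(fields)), collapse = "")
    wl(do.call(sprintf, c(list(fmt), asplit(fields, 2L))))
  }
  .write_elem("*ELEMENT_SOLID", mesh$solids)
  .write_elem("*ELEMENT_SHELL", mesh$shells)
  .write_elem("*ELEMENT_BEAM", mesh$beams)
  wl("*END")
  invisible(path)
}
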