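test_that("keyword files round-trip the unit cube in both dialects", {
  cube <- unit_cube_mesh()
  p <- withr::local_tempfile(fileext = ".k")
  write_keyword_mesh(cube, p)
  back <- read_keyword_mesh(p)
  expect_identical(back$node_ids, cube$node_ids)
  expect_identical(back$solids$conn, cube$solids$conn)
  expect_equal(back$coords, cube$coords, tolerance = 1e-12)
  expect_identical(nrow(back$shells$conn), 0L)

  # same content, comma-separated dialect
  pc <- withr::local_tempfile(fileext = ".k")
  writeLines(c("*KEYWORD", "*NODE",
               sprintf("%d,%g,%g,%g", cube$node_ids, cube$coords[, 1],
                       cube$coords[, 2], cube$coords[, 3]),
               "*ELEMENT_SOLID",
               paste(c(1, 1, 1:8), collapse = ","), "*END"), pc)
  comma <- read_keyword_mesh(pc)
  expect_identical(comma$node_ids, cube$node_ids)
  expect_identical(comma$solids$conn, cube$solids$conn)
  expect_equal(comma$coords, cube$coords)
})

test_that("the limb fixture survives a write/read round trip", {
  mesh <- small_limb()$mesh
  p <- withr::local_tempfile(fileext = ".k")
  write_keyword_mesh(mesh, p)
  back <- read_keyword_mesh(p)
  expect_identical(back$node_ids, mesh$node_ids)
  expect_identical(back$solids$conn, mesh$solids$conn)
  expect_identical(back$solids$pid, mesh$solids$pid)
  expect_identical(back$shells$conn, mesh$shells$conn)
  expect_identical(back$beams$conn, mesh$beams$conn)
  scale <- max(abs(mesh$coords))
  expect_lt(max(abs(back$coords - mesh$coords)) / scale, 1e-7)
  expect_identical(back$part_names[["4"]], "organ")
})

test_that("malformed keyword input fails loudly", {
  p <- withr::local_tempfile(fileext = ".k")
  writeLines(c("*KEYWORD", "*NODE", "1,0,0,0", "1,1,0,0",
               "*ELEMENT_SOLID", paste(c(1, 1, rep(1, 8)), collapse = ","),
               "*END"), p)
  expect_error(read_keyword_mesh(p), "duplicate node ID")

  writeLines(c("*KEYWORD", "*NODE", "1,0,0,0",
               "*ELEMENT_SOLID", paste(c(1, 1, rep(9, 8)), collapse = ","),
               "*END"), p)
  expect_error(read_keyword_mesh(p), "missing node")

  writeLines(character(0), p)
  expect_error(read_keyword_mesh(p), "empty")

  cube <- unit_cube_mesh()
  write_keyword_mesh(cube, p)
  txt <- readLines(p)
  writeLines(append(txt, c("*MAT_ELASTIC", "1,2.0,0.3"),
                    after = length(txt) - 1L), p)
  expect_warning(back <- read_keyword_mesh(p), "MAT_ELASTIC")
  expect_identical(back$solids$conn, cube$solids$conn)
})

test_that("degenerate (collapsed) solids pass through verbatim", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  conn <- matrix(c(1L, 2L, 3L, 4L, 4L, 4L, 4L, 4L), 1L)
  tet <- fe_mesh(1:4, xyz, solids = list(conn = conn, eid = 5L, pid = 2L))
  p <- withr::local_tempfile(fileext = ".k")
  write_keyword_mesh(tet, p)
  back <- read_keyword_mesh(p)
  expect_identical(back$solids$conn, conn)
  expect_identical(back$solids$eid, 5L)
})

test_that("surface extraction finds boundary faces", {
  cube <- unit_cube_mesh()
  s <- extract_surface(cube, 1L)
  expect_identical(nrow(s$faces), 6L)
  expect_identical(s$node_ids, 1:8)

  blk <- block_mesh(3L) # 2x2x2 elements, 27 nodes
  sb <- extract_surface(blk, 1L)
  expect_identical(nrow(sb$faces), 24L)
  expect_identical(length(sb$node_ids), 26L) # centre node excluded

  # Euler characteristic of the closed block surface
  edges <- rbind(sb$faces[, 1:2], sb$faces[, 2:3], sb$faces[, 3:4],
                 sb$faces[, c(4, 1)])
  ekey <- unique(paste(pmin(edges[, 1], edges[, 2]),
                       pmax(edges[, 1], edges[, 2])))
  expect_identical(length(sb$node_ids) - length(ekey) + nrow(sb$faces), 2L)

  expect_error(extract_surface(cube, 99L), "unknown part")
})

test_that("hollow parts yield two disjoint face shells matching brute force", {
  limb <- small_limb()
  mesh <- limb$mesh
  s <- extract_surface(mesh, limb$parts$organ)
  # brute force: faces referenced exactly once within the organ part
  conn <- mesh$solids$conn[mesh$solids$pid == limb$parts$organ, ,
                           drop = FALSE]
  fidx <- rbind(c(1, 2, 3, 4), c(5, 8, 7, 6), c(1, 5, 6, 2),
                c(2, 6, 7, 3), c(3, 7, 8, 4), c(4, 8, 5, 1))
  keys <- character(0)
  for (r in seq_len(nrow(conn))) for (f in 1:6)
    keys <- c(keys, paste(sort(conn[r, fidx[f, ]]), collapse = "_"))
  once <- sum(table(keys) == 1L)
  expect_identical(nrow(s$faces), once)
  expect_setequal(s$node_ids,
                  unique(as.vector(conn))[unique(as.vector(conn)) %in%
                                            as.vector(s$faces)])
})

test_that("surface extraction is independent of element order", {
  blk <- block_mesh(3L)
  perm <- sample(nrow(blk$solids$conn))
  shuffled <- fe_mesh(blk$node_ids, blk$coords,
                      solids = list(conn = blk$solids$conn[perm, ],
                                    eid = blk$solids$eid[perm],
                                    pid = blk$solids$pid[perm]))
  a <- extract_surface(blk, 1L)
  b <- extract_surface(shuffled, 1L)
  expect_identical(a$node_ids, b$node_ids)
  key <- function(f) sort(apply(f, 1L, function(r)
    paste(sort(r), collapse = "_")))
  expect_identical(key(a$faces), key(b$faces))
})

test_that("OBJ export writes vertices, faces and the node-ID sidecar", {
  cube <- unit_cube_mesh()
  s <- extract_surface(cube, 1L)
  p <- withr::local_tempfile(fileext = ".obj")
  export_surface_obj(s, cube, p)
  lines <- readLines(p)
  expect_identical(sum(startsWith(lines, "v ")), 8L)
  expect_identical(sum(startsWith(lines, "f ")), 6L)
  back <- read_surface_obj(p)
  expect_equal(back$coords, cube$coords, tolerance = 1e-9)
  expect_identical(back$node_ids, s$node_ids)

  limb <- small_limb()
  skin <- extract_surface(limb$mesh, limb$parts$skin)
  p2 <- withr::local_tempfile(fileext = ".obj")
  export_surface_obj(skin, limb$mesh, p2)
  expect_identical(nrow(read_surface_obj(p2)$coords),
                   length(skin$node_ids))

  bad <- s; bad$faces[1L, 1L] <- 999L
  expect_error(export_surface_obj(bad, cube, p), "outside the surface")
})
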