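test_that("a single hex yields the complete within-element graph", {
  g <- build_graph(unit_cube_mesh(), epsilon = 1e-8)
  expect_identical(nrow(g$edges), 28L) # choose(8, 2)
  deg_counts <- tabulate(c(g$edges[, 1], g$edges[, 2]), 8L)
  expect_true(all(deg_counts == 7L))
  # direct substitution in the weight formula for an edge of length 2
  two <- fe_mesh(1:2, rbind(c(0, 0, 0), c(2, 0, 0)),
                 beams = list(conn = matrix(1:2, 1L), eid = 1L, pid = 1L))
  gw <- build_graph(two, epsilon = 1e-8)
  expect_equal(gw$weights, 1 / (8 + 1e-8), tolerance = 1e-15)
})

test_that("adjacency equals brute-force within-element pair enumeration", {
  # two hexes sharing a face: 12 nodes
  xyz <- as.matrix(expand.grid(x = 0:2, y = 0:1, z = 0:1))
  ids <- 1:12
  nid <- function(i, j, k) k * 6 + j * 3 + i + 1
  conn <- rbind(
    c(nid(0, 0, 0), nid(1, 0, 0), nid(1, 1, 0), nid(0, 1, 0),
      nid(0, 0, 1), nid(1, 0, 1), nid(1, 1, 1), nid(0, 1, 1)),
    c(nid(1, 0, 0), nid(2, 0, 0), nid(2, 1, 0), nid(1, 1, 0),
      nid(1, 0, 1), nid(2, 0, 1), nid(2, 1, 1), nid(1, 1, 1)))
  mesh <- fe_mesh(ids, xyz, solids = list(conn = conn, eid = 1:2,
                                          pid = c(1L, 1L)))
  g <- build_graph(mesh)
  brute <- unique(do.call(rbind, lapply(1:2, function(e) {
    p <- t(utils::combn(conn[e, ], 2L))
    cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  })))
  got <- cbind(g$node_ids[g$edges[, 1]], g$node_ids[g$edges[, 2]])
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]),
                                pmax(m[, 1], m[, 2])))
  expect_identical(key(got), key(brute))
  # degrees match pairwise enumeration
  w_of <- function(a, b) 1 / (sqrt(sum((xyz[a, ] - xyz[b, ])^2))^3 + 1e-8)
  for (i in c(1L, 2L, 5L)) {
    nbrs <- unique(c(brute[brute[, 1] == i, 2], brute[brute[, 2] == i, 1]))
    expect_equal(g$degrees[i], sum(vapply(nbrs, w_of, numeric(1), a = i)),
                 tolerance = 1e-12)
  }
})

test_that("differential coordinates satisfy their definition", {
  blk <- block_mesh(3L)
  g <- build_graph(blk)
  delta <- differential_coordinates(g)
  # definitional identity delta = L V
  expect_equal(delta, as.matrix(g$L %*% blk$coords), tolerance = 1e-12)
  # centre node of the 3x3x3 grid: brute-force double loop over neighbours
  ctr <- which(colSums(t(blk$coords) == c(1, 1, 1)) == 3L)
  nbrs <- unique(c(g$edges[g$edges[, 1] == ctr, 2],
                   g$edges[g$edges[, 2] == ctr, 1]))
  expect_identical(length(nbrs), 26L)
  acc <- c(0, 0, 0)
  for (j in nbrs) {
    d <- sqrt(sum((blk$coords[ctr, ] - blk$coords[j, ])^2))
    acc <- acc + (blk$coords[ctr, ] - blk$coords[j, ]) / (d^3 + 1e-8)
  }
  expect_equal(unname(delta[ctr, ]), unname(acc), tolerance = 1e-12)
  # symmetric neighbourhood => zero differential coordinate
  expect_equal(max(abs(delta[ctr, ])), 0, tolerance = 1e-12)
})

test_that("Laplacian structure: zero row sums, symmetry, anchored SPD", {
  g <- build_graph(block_mesh(3L))
  expect_lt(max(abs(Matrix::rowSums(g$L))), 1e-10)
  expect_lt(max(abs(g$L - Matrix::t(g$L))), 1e-12)
  sys <- partition_system(g, constrained_ids = c(1L, 27L))
  ev <- eigen(as.matrix(sys$L_FF), symmetric = TRUE, only.values = TRUE)
  expect_gt(min(ev$values), 0)
})

test_that("partition handles edge cases and unconstrained islands", {
  blk <- block_mesh(3L)
  g <- build_graph(blk)
  all_con <- partition_system(g, blk$node_ids)
  expect_identical(length(all_con$free_idx), 0L)
  sol <- solve_positions(all_con, blk$coords)
  expect_identical(sol$coords, blk$coords)

  # one free node with fully constrained hex neighbours: L_FF is its degree
  cube <- fe_mesh(1:9, rbind(unit_cube_mesh()$coords, c(0.5, 0.5, 0.5)),
                  solids = list(conn = rbind(matrix(1:8, 1L),
                                             matrix(c(1:4, 5:7, 9L), 1L)),
                                eid = 1:2, pid = c(1L, 1L)))
  gc <- build_graph(cube)
  sys1 <- partition_system(gc, 1:8)
  expect_identical(length(sys1$free_idx), 1L)
  expect_equal(as.numeric(sys1$L_FF), gc$degrees[sys1$free_idx])

  # a disconnected organ with no constraint is rejected by name
  limb <- small_limb()
  m <- limb$mesh
  no_tether <- fe_mesh(m$node_ids, m$coords, solids = m$solids,
                       shells = m$shells, part_names = m$part_names)
  gi <- build_graph(no_tether)
  skin <- extract_surface(m, limb$parts$skin)
  expect_error(partition_system(gi, skin$node_ids, no_tether),
               "unconstrained island.*organ")
})

test_that("identity recovery and translation equivariance hold", {
  limb <- small_limb()
  mesh <- limb$mesh
  g <- build_graph(mesh)
  skin <- extract_surface(mesh, limb$parts$skin)
  bone <- extract_surface(mesh, limb$parts$bone)
  organ <- extract_surface(mesh, limb$parts$organ)
  con <- sort(unique(c(skin$node_ids, bone$node_ids, organ$node_ids)))
  sys <- partition_system(g, con, mesh)
  orig_fixed <- mesh$coords[sys$fixed_idx, , drop = FALSE]

  sol <- solve_positions(sys, orig_fixed)
  expect_lt(max(abs(sol$coords - mesh$coords)),
            1e-8 * bbox_diagonal(mesh))

  t_vec <- c(3.5, -2.25, 11)
  sol_t <- solve_positions(sys, sweep(orig_fixed, 2L, t_vec, "+"))
  moved <- sweep(sol_t$coords, 2L, t_vec, "-")
  expect_lt(max(abs(moved - sol$coords)), 1e-9)

  # scaling equivariance must NOT hold (weights fix the original scale)
  sol_s <- solve_positions(sys, 2 * orig_fixed)
  expect_gt(max(abs(sol_s$coords - 2 * sol$coords)), 1e-6)
})

test_that("CG matches a dense direct solve and row scaling is immaterial", {
  blk <- block_mesh(5L) # 125 nodes
  g <- build_graph(blk)
  boundary <- blk$node_ids[rowSums(blk$coords == 0 | blk$coords == 4) > 0]
  sys <- partition_system(g, boundary)
  # a non-trivial pose: twist the boundary
  th <- 0.3 * blk$coords[sys$fixed_idx, 3L]
  fixed <- blk$coords[sys$fixed_idx, , drop = FALSE]
  fixed2 <- cbind(fixed[, 1] * cos(th) - fixed[, 2] * sin(th),
                  fixed[, 1] * sin(th) + fixed[, 2] * cos(th),
                  fixed[, 3])
  cg <- solve_positions(sys, fixed2, tol = 1e-12)
  expect_identical(cg$method, "cg")

  L <- as.matrix(g$L)
  fi <- sys$free_idx; ci <- sys$fixed_idx
  delta <- L %*% blk$coords
  rhs <- delta[fi, ] - L[fi, ci] %*% fixed2
  dense <- solve(L[fi, fi], rhs)
  expect_lt(max(abs(cg$coords[fi, ] - dense)), 1e-8)

  # row-normalised equations (each row divided by its degree) solve the same
  sc <- 1 / g$degrees[fi]
  dense_norm <- solve(sc * L[fi, fi], sc * rhs)
  expect_lt(max(abs(dense_norm - dense)), 1e-9)

  direct <- solve_positions(sys, fixed2, method = "direct")
  expect_lt(max(abs(direct$coords[fi, ] - dense)), 1e-8)
})

test_that("harmonic solves obey the discrete maximum principle", {
  blk <- block_mesh(4L)
  g <- build_graph(blk)
  boundary <- blk$node_ids[rowSums(blk$coords == 0 | blk$coords == 3) > 0]
  sys <- partition_system(g, boundary)
  sys$delta[] <- 0 # pure harmonic interpolation of the boundary
  set.seed(11)
  fixed <- matrix(runif(3 * length(sys$fixed_idx), -5, 5), ncol = 3L)
  sol <- solve_positions(sys, fixed, tol = 1e-12)
  free_vals <- sol$coords[sys$free_idx, , drop = FALSE]
  for (ax in 1:3) {
    expect_gte(min(free_vals[, ax]), min(fixed[, ax]) - 1e-8)
    expect_lte(max(free_vals[, ax]), max(fixed[, ax]) + 1e-8)
  }
})

test_that("isolated nodes are excluded but carried through unmoved", {
  cube <- unit_cube_mesh()
  mesh <- fe_mesh(1:9, rbind(cube$coords, c(9, 9, 9)),
                  solids = cube$solids)
  expect_message(g <- build_graph(mesh), "isolated")
  expect_identical(g$isolated, 9L)
  delta <- differential_coordinates(g)
  expect_true(all(is.na(delta[9L, ])))
  sys <- partition_system(g, 1:4)
  sol <- solve_positions(sys, mesh$coords[1:4, ])
  expect_identical(sol$coords[9L, ], mesh$coords[9L, ])
})
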