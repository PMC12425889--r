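test_that("surface constraints assemble with conflict detection", {
  limb <- small_limb()
  mesh <- limb$mesh
  skin <- extract_surface(mesh, limb$parts$skin, name = "skin")
  bone <- extract_surface(mesh, limb$parts$bone, name = "skeleton")
  at <- function(s) mesh$coords[node_index(mesh, s$node_ids), ,
                                drop = FALSE]

  # identity pose: constraints equal original coordinates, union of sets
  cs <- assemble_surface_constraints(mesh, list(
    list(surface = skin, coords = at(skin)),
    list(surface = bone, coords = at(bone))))
  expect_setequal(cs$ids, union(skin$node_ids, bone$node_ids))
  expect_equal(cs$targets,
               mesh$coords[node_index(mesh, cs$ids), , drop = FALSE])
  expect_true(all(cs$tags == "surface"))

  # posed surfaces from LBS agree on shared nodes: zero conflicts
  ps <- pose_limb_surfaces(limb, 45)
  cs45 <- assemble_surface_constraints(mesh, ps$posed_surfaces)
  expect_identical(length(cs45$ids),
                   length(union(skin$node_ids, bone$node_ids)))

  # conflicting duplicates are an error naming the node
  bad <- at(bone); bad[1L, ] <- bad[1L, ] + 5
  expect_error(assemble_surface_constraints(mesh, list(
    list(surface = skin, coords = at(skin)),
    list(surface = bone, coords = bad))), "conflicting")

  expect_error(constraint_set(1:2, rbind(c(0, 0, 0), c(NA, 0, 0))),
               "non-finite")
})

test_that("disjoint surfaces union their entries", {
  cube <- unit_cube_mesh()
  blk <- block_mesh(3L)
  s <- extract_surface(blk, 1L)
  cs <- assemble_surface_constraints(blk, list(
    list(surface = s, coords = blk$coords[node_index(blk, s$node_ids), ])))
  expect_identical(length(cs$ids), 26L)
})

test_that("extra-node prediction reproduces rigid motions exactly", {
  limb <- small_limb()
  mesh <- limb$mesh
  skin <- extract_surface(mesh, limb$parts$skin)
  bone <- extract_surface(mesh, limb$parts$bone)
  con_ids <- union(skin$node_ids, bone$node_ids)
  set.seed(9)
  R <- random_rotation(); t_vec <- c(4, -7, 2)
  rigid <- function(x) x %*% t(R) + rep(t_vec, each = nrow(x))
  cs <- constraint_set(con_ids,
                       rigid(mesh$coords[node_index(mesh, con_ids), ]))
  cand <- limb$interface_ids$organ
  out <- predict_extra_nodes(mesh, cs, cand, k = 30L)
  expect_setequal(out$ids, union(con_ids, cand))
  got <- out$targets[match(cand, out$ids), , drop = FALSE]
  want <- rigid(mesh$coords[node_index(mesh, cand), , drop = FALSE])
  expect_lt(max(abs(got - want)), 1e-6)
  expect_true(all(out$tags[match(cand, out$ids)] == "extra"))

  # idempotence: re-running on its own output adds nothing
  again <- predict_extra_nodes(mesh, out, cand, k = 30L)
  expect_identical(again$ids, out$ids)
  expect_identical(again$targets, out$targets)

  # a candidate coincident with a constrained node inherits its target
  dup_pos <- mesh$coords[node_index(mesh, con_ids[1L]), , drop = FALSE]
  mesh2 <- fe_mesh(c(mesh$node_ids, 99999L), rbind(mesh$coords, dup_pos),
                   solids = mesh$solids, shells = mesh$shells,
                   beams = list(conn = matrix(c(99999L, con_ids[1L]), 1L),
                                eid = 99998L, pid = 5L))
  out2 <- predict_extra_nodes(mesh2, cs, 99999L, k = 30L)
  expect_equal(out2$targets[match(99999L, out2$ids), ],
               cs$targets[1L, ], tolerance = 1e-6)

  expect_error(predict_extra_nodes(mesh, cs, cand, k = 4L), "at least 5")
  few <- constraint_set(con_ids[1:10],
                        mesh$coords[node_index(mesh, con_ids[1:10]), ])
  w <- capture_warnings(predict_extra_nodes(mesh, few, cand[1:3],
                                            k = 30L))
  expect_match(w, "using all", all = FALSE)
})

test_that("local predictions track a global TPS away from the joint", {
  limb <- small_limb()
  mesh <- limb$mesh
  ps <- pose_limb_surfaces(limb, 30)
  cs <- assemble_surface_constraints(mesh, ps$posed_surfaces)
  cand <- limb$interface_ids$flesh_wall
  local <- predict_extra_nodes(mesh, cs, cand, k = 40L)
  src <- mesh$coords[node_index(mesh, cs$ids), , drop = FALSE]
  global <- fit_tps(src, cs$targets, ridge = 1e-6)
  want <- predict(global, mesh$coords[node_index(mesh, cand), ,
                                      drop = FALSE])
  got <- local$targets[match(cand, local$ids), , drop = FALSE]
  expect_true(all(is.finite(got)))
  gap <- sqrt(rowSums((got - want)^2))
  expect_lt(stats::median(gap), 1.0) # within an edge length of each other
})

test_that("interface candidate selection matches brute-force distances", {
  limb <- small_limb()
  mesh <- limb$mesh
  expect_identical(select_interface_candidates(mesh, limb$parts$organ,
                                               limb$parts$bone, 0),
                   integer(0))
  all_organ <- select_interface_candidates(mesh, limb$parts$organ,
                                           limb$parts$bone, Inf)
  expect_setequal(all_organ, limb$interface_ids$organ)

  thr <- 5
  got <- select_interface_candidates(mesh, limb$parts$organ,
                                     limb$parts$bone, thr)
  bone_surf <- extract_surface(mesh, limb$parts$bone)
  bxyz <- mesh$coords[node_index(mesh, bone_surf$node_ids), , drop = FALSE]
  brute <- Filter(function(id) {
    p <- mesh$coords[node_index(mesh, id), ]
    min(sqrt(colSums((t(bxyz) - p)^2))) <= thr
  }, limb$interface_ids$organ)
  expect_setequal(got, as.integer(brute))
})

test_that("constraint sets and ID lists round-trip through files", {
  cs <- constraint_set(c(3L, 8L, 21L),
                       rbind(c(0.125, -2, 3), c(1, 2, 3), c(-4.5, 0, 9)),
                       tags = c("surface", "surface", "extra"))
  p <- withr::local_tempfile(fileext = ".json")
  write_constraints(cs, p)
  back <- read_constraints(p)
  expect_identical(back$ids, cs$ids)
  expect_equal(back$targets, cs$targets)
  expect_identical(back$tags, cs$tags)

  pid <- withr::local_tempfile(fileext = ".txt")
  write_id_list(c(5L, 7L, 2L), pid)
  expect_identical(read_id_list(pid), c(5L, 7L, 2L))
})
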