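# small meshes built in code, shared across test files

unit_cube_mesh <- function() {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  fe_mesh(1:8, xyz,
          solids = list(conn = matrix(1:8, 1L), eid = 1L, pid = 1L),
          part_names = c("1" = "cube"))
}

# (n-1)^3 hex elements on an n^3 node grid with unit spacing
block_mesh <- function(n = 3L) {
  g <- expand.grid(x = 0:(n - 1L), y = 0:(n - 1L), z = 0:(n - 1L))
  nid <- function(i, j, k) (k * n + j) * n + i + 1L
  e <- expand.grid(i = 0:(n - 2L), j = 0:(n - 2L), k = 0:(n - 2L))
  conn <- cbind(nid(e$i, e$j, e$k), nid(e$i + 1L, e$j, e$k),
                nid(e$i + 1L, e$j + 1L, e$k), nid(e$i, e$j + 1L, e$k),
                nid(e$i, e$j, e$k + 1L), nid(e$i + 1L, e$j, e$k + 1L),
                nid(e$i + 1L, e$j + 1L, e$k + 1L),
                nid(e$i, e$j + 1L, e$k + 1L))
  fe_mesh(seq_len(n^3), as.matrix(g),
          solids = list(conn = conn, eid = seq_len(nrow(conn)),
                        pid = rep(1L, nrow(conn))))
}

# coarse two-segment limb for fast module tests (not the study fixture)
small_limb_spec <- function(...) {
  defaults <- list(seg_length = c(30, 30), joint_gap = 16, r_marrow = 3,
                   r_bone = 6, r_flesh = 10, n_circ = 12L,
                   n_rad_bone = 1L, n_rad_flesh = 2L, axial_size = 4,
                   organ_radius = 2.5, organ_inner_radius = 1.2,
                   organ_length = 12, blend_band = 20)
  do.call(limb_spec, utils::modifyList(defaults, list(...)))
}

.memo <- new.env(parent = emptyenv())

small_limb <- function() {
  if (is.null(.memo$small)) .memo$small <- generate_limb(small_limb_spec())
  .memo$small
}

default_limb <- function() {
  if (is.null(.memo$default)) .memo$default <- generate_limb(limb_spec())
  .memo$default
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# independent corner-determinant routine for hexes (the oracle used by the
# quality tests; written straight from the definition, not shared with R/)
oracle_hex_jacobian <- function(v) {
  nb <- list(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
             c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))
  vals <- vapply(1:8, function(c0) {
    e <- t(vapply(nb[[c0]], function(a) v[a, ] - v[c0, ], numeric(3)))
    lens <- sqrt(rowSums(e^2))
    det(t(e)) / prod(lens)
  }, numeric(1))
  min(vals)
}
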