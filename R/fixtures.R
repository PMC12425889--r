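#' Define an articulated armature
#'
#' A minimal joint hierarchy: each joint is a rotation about an axis
#' through a pivot point, composed with its parent's transform. Joint 1 is
#' conventionally the root (identity when its angle is 0).
#'
#' @param pivots m x 3 matrix of pivot points.
#' @param axes m x 3 matrix of rotation axes (normalised internally).
#' @param angles rotation angles in degrees.
#' @param parents integer vector; 0 for a root joint, otherwise the index
#'   of the parent joint (which must come earlier: acyclic by
#'   construction).
#' @return an `armature`.
#' @export
armature <- function(pivots, axes, angles, parents) {
  pivots <- matrix(as.numeric(pivots), ncol = 3L)
  axes <- matrix(as.numeric(axes), ncol = 3L)
  lens <- sqrt(rowSums(axes^2))
  if (any(lens == 0)) stop("zero-length rotation axis")
  axes <- axes / lens
  parents <- as.integer(parents)
  if (any(parents >= seq_along(parents)))
    stop("parents must precede their children (acyclic hierarchy)")
  structure(list(pivots = pivots, axes = axes,
                 angles = as.numeric(angles), parents = parents),
            class = "armature")
}

.rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# world transforms (R, t) per joint: x -> R x + t
.joint_transforms <- function(arm) {
  m <- length(arm$angles)
  Rs <- vector("list", m); ts <- vector("list", m)
  for (j in seq_len(m)) {
    Rl <- .rotation_matrix(arm$axes[j, ], arm$angles[j])
    tl <- as.numeric(arm$pivots[j, ] - Rl %*% arm$pivots[j, ])
    p <- arm$parents[j]
    if (p == 0L) {
      Rs[[j]] <- Rl; ts[[j]] <- tl
    } else {
      Rs[[j]] <- Rs[[p]] %*% Rl
      ts[[j]] <- as.numeric(Rs[[p]] %*% tl) + ts[[p]]
    }
  }
  list(R = Rs, t = ts)
}

#' Pose coordinates by linear blend skinning
#'
#' Each node maps to the blend of its joints' rigid transforms (composed
#' along the hierarchy) applied to its rest position:
#' \eqn{v' = \sum_j w_{ij} (R_j v + t_j)}. Nodes with weight 1 on a single
#' joint move exactly rigidly; blended nodes exhibit the usual
#' linear-blend thinning near bent joints — which is precisely the
#' behaviour the positioning pipeline must cope with.
#'
#' @param coords n x 3 rest coordinates.
#' @param arm an [armature()].
#' @param weights n x m matrix of skinning weights (rows sum to 1).
#' @return n x 3 posed coordinates.
#' @export
pose_lbs <- function(coords, arm, weights) {
  coords <- as.matrix(coords)
  weights <- as.matrix(weights)
  if (nrow(weights) != nrow(coords) ||
      ncol(weights) != length(arm$angles))
    stop("weights must be (n nodes) x (n joints)")
  s <- rowSums(weights)
  if (any(abs(s - 1) > 1e-9))
    stop("node(s) without a full weight set: rows ",
         paste(utils::head(which(abs(s - 1) > 1e-9), 5L), collapse = ", "))
  tf <- .joint_transforms(arm)
  out <- matrix(0, nrow(coords), 3L)
  for (j in seq_along(arm$angles)) {
    wj <- weights[, j]
    if (all(wj == 0)) next
    pj <- coords %*% t(tf$R[[j]])
    pj <- sweep(pj, 2L, tf$t[[j]], "+")
    out <- out + wj * pj
  }
  out
}

#' Specification for the synthetic two-segment limb fixture
#'
#' Describes an articulated "limb": two segments along +z joined by a
#' hinge. Each segment has a tubular bone core (hexahedra between
#' `r_marrow` and `r_bone`), a flesh annulus (hexahedra between `r_bone`
#' and `r_flesh`, continuous across the joint gap), and a quad-shell skin
#' on the outer flesh surface, closed with end caps. An optional
#' disconnected "organ" (a small hex tube) floats in the joint cavity,
#' tethered to the lower bone-end ring by a few beam elements so the
#' Laplacian graph stays connected — emulating anatomically adjacent but
#' topologically unconnected components. Defaults give a mesh of roughly
#' 23k nodes / 20k elements in millimetre units.
#'
#' @param seg_length lengths of the two segments (mm). Default `c(100, 100)`.
#' @param joint_gap axial gap between the bone ends at the joint. Must
#'   exceed `2 * r_bone * tan(angle/2)` for the largest intended hinge
#'   angle, or the rigidly posed bone ends collide through the flesh at the
#'   inner corner. Default 40 (collision-free up to 90 degrees with 20 mm
#'   margin).
#' @param r_marrow,r_bone,r_flesh nested radii (marrow cavity, bone outer,
#'   flesh/skin outer). Defaults 5, 10, 20.
#' @param n_circ circumferential divisions (divisible by 4). Default 24.
#' @param n_rad_bone,n_rad_flesh radial element layers in bone and flesh.
#'   Defaults 2 and 5.
#' @param axial_size target axial element height. Default 2.
#' @param organ logical: include the organ inclusion. Default `TRUE`.
#' @param organ_radius,organ_inner_radius,organ_length organ tube geometry.
#'   Defaults 4, 2, 28. The tube must stay slender relative to the gap: at
#'   a 90-degree bend its inner fibre compresses by roughly
#'   `organ_radius / (organ_length / (pi/2))`.
#' @param organ_offset 2-vector (x, y) offset of the organ axis. Default
#'   `c(0, 0)`.
#' @param blend_band axial width of the skinning transition band centred on
#'   the hinge. Must exceed `1.5 * r_flesh * angle` (radians) or the
#'   inner-side skin folds over itself under linear blend skinning; values
#'   close to `joint_gap` keep the skin-versus-rigid-bone mismatch near the
#'   bone ends small. Default 70.
#' @param jitter coordinate jitter applied to interior flesh nodes, as a
#'   fraction of `axial_size`. Default 0.02.
#' @param seed integer RNG seed for the jitter. Default 1.
#' @return a `limb_spec` list.
#' @export
limb_spec <- function(seg_length = c(100, 100), joint_gap = 40,
                      r_marrow = 5, r_bone = 10, r_flesh = 20,
                      n_circ = 24L, n_rad_bone = 2L, n_rad_flesh = 5L,
                      axial_size = 2, organ = TRUE, organ_radius = 4,
                      organ_inner_radius = 2, organ_length = 28,
                      organ_offset = c(0, 0), blend_band = 70,
                      jitter = 0.02, seed = 1L) {
  stopifnot(r_marrow > 0, r_bone > r_marrow, r_flesh > r_bone,
            n_circ >= 8L, n_circ %% 4L == 0L, n_rad_bone >= 1L,
            n_rad_flesh >= 2L, joint_gap > 0, all(seg_length > 0))
  if (organ) stopifnot(organ_radius < r_bone,
                       organ_inner_radius < organ_radius,
                       organ_length < joint_gap + 2 * axial_size)
  structure(as.list(environment()), class = "limb_spec")
}

#' Generate the articulated limb fixture
#'
#' Deterministic for a given spec (the jitter RNG is seeded and restored).
#' Part IDs: 1 bone, 2 flesh, 3 skin (shells, closed with caps), 4 organ,
#' 5 tether beams.
#'
#' @param spec a [limb_spec()].
#' @return list: `mesh` ([fe_mesh()]), `parts` (named part-ID list),
#'   `armature` (hinge at the joint, angles 0), `weights` (node x joint
#'   skinning matrix), `interface_ids` (ground-truth interface node IDs:
#'   `organ` = all organ nodes, `flesh_wall` = flesh inner-wall nodes
#'   inside the gap band), `spec`.
#' @export
generate_limb <- function(spec = limb_spec()) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  L1 <- spec$seg_length[1L]; L2 <- spec$seg_length[2L]
  g <- spec$joint_gap
  z_hinge <- L1 + g / 2
  zs <- unique(c(
    seq(0, L1, length.out = max(2L, round(L1 / spec$axial_size)) + 1L),
    seq(L1, L1 + g, length.out = max(2L, round(g / spec$axial_size)) + 1L),
    seq(L1 + g, L1 + g + L2,
        length.out = max(2L, round(L2 / spec$axial_size)) + 1L)))
  nrb <- spec$n_rad_bone; nrf <- spec$n_rad_flesh
  rs <- c(seq(spec$r_marrow, spec$r_bone, length.out = nrb + 1L),
          seq(spec$r_bone, spec$r_flesh, length.out = nrf + 1L)[-1L])
  nc <- as.integer(spec$n_circ)
  nz <- length(zs); nr <- length(rs)
  th <- 2 * pi * (seq_len(nc) - 1L) / nc

  nid <- function(iz, ir, ic) {
    ic <- (ic - 1L) %% nc + 1L
    ((iz - 1L) * nr + (ir - 1L)) * nc + ic
  }
  # full cylindrical grid (unused rows pruned at the end)
  grid <- expand.grid(ic = seq_len(nc), ir = seq_len(nr), iz = seq_len(nz))
  gid <- nid(grid$iz, grid$ir, grid$ic)
  gx <- rs[grid$ir] * cos(th[grid$ic])
  gy <- rs[grid$ir] * sin(th[grid$ic])
  gz <- zs[grid$iz]
  coords <- cbind(gx, gy, gz)[order(gid), ]
  ids <- sort(gid)

  # jitter interior flesh nodes (not walls, not skin, not end stations)
  interior <- grid$ir > nrb + 1L & grid$ir < nr &
    grid$iz > 1L & grid$iz < nz
  interior <- interior[order(gid)]
  amp <- spec$jitter * spec$axial_size
  if (amp > 0 && any(interior))
    coords[interior, ] <- coords[interior, ] +
      matrix(stats::runif(3L * sum(interior), -amp, amp), ncol = 3L)

  # ---- solids ------------------------------------------------------------
  lay <- expand.grid(ic = seq_len(nc), ir = seq_len(nr - 1L),
                     iz = seq_len(nz - 1L))
  zmid <- (zs[lay$iz] + zs[lay$iz + 1L]) / 2
  in_gap <- zmid > L1 & zmid < L1 + g
  is_bone <- lay$ir <= nrb
  keep <- !(is_bone & in_gap) # bone is absent across the joint gap
  lay <- lay[keep, ]; is_bone <- is_bone[keep]
  hex <- cbind(nid(lay$iz, lay$ir, lay$ic),
               nid(lay$iz, lay$ir + 1L, lay$ic),
               nid(lay$iz, lay$ir + 1L, lay$ic + 1L),
               nid(lay$iz, lay$ir, lay$ic + 1L),
               nid(lay$iz + 1L, lay$ir, lay$ic),
               nid(lay$iz + 1L, lay$ir + 1L, lay$ic),
               nid(lay$iz + 1L, lay$ir + 1L, lay$ic + 1L),
               nid(lay$iz + 1L, lay$ir, lay$ic + 1L))
  solid_pid <- ifelse(is_bone, 1L, 2L)

  # ---- skin shells: lateral + end caps -----------------------------------
  latg <- expand.grid(ic = seq_len(nc), iz = seq_len(nz - 1L))
  lateral <- cbind(nid(latg$iz, nr, latg$ic),
                   nid(latg$iz, nr, latg$ic + 1L),
                   nid(latg$iz + 1L, nr, latg$ic + 1L),
                   nid(latg$iz + 1L, nr, latg$ic))
  capg <- expand.grid(ic = seq_len(nc), ir = seq_len(nr - 1L),
                      iz = c(1L, nz))
  caps <- cbind(nid(capg$iz, capg$ir, capg$ic),
                nid(capg$iz, capg$ir + 1L, capg$ic),
                nid(capg$iz, capg$ir + 1L, capg$ic + 1L),
                nid(capg$iz, capg$ir, capg$ic + 1L))
  # close the marrow hole at each end with a transfinite (Coons) quad
  # patch whose boundary is the innermost node ring: all-quad, well-shaped
  patch1 <- .disk_patch(nc, spec$r_marrow, th, zs[1L],
                        first_id = nz * nr * nc + 1L,
                        ring_ids = nid(1L, 1L, seq_len(nc)))
  patch2 <- .disk_patch(nc, spec$r_marrow, th, zs[nz],
                        first_id = patch1$next_id,
                        ring_ids = nid(nz, 1L, seq_len(nc)))
  shells <- rbind(lateral, caps, patch1$quads, patch2$quads)
  shell_pid <- rep(3L, nrow(shells))

  extra_ids <- c(patch1$ids, patch2$ids)
  extra_coords <- rbind(patch1$coords, patch2$coords)
  id_last_patch <- patch2$next_id - 1L

  # ---- organ -------------------------------------------------------------
  organ_hex <- NULL; beams <- NULL
  organ_ids <- integer(0)
  if (spec$organ) {
    o0 <- id_last_patch # organ IDs start after o0
    nro <- 1L; nco <- 12L
    noz <- max(2L, round(spec$organ_length / spec$axial_size))
    ors <- seq(spec$organ_inner_radius, spec$organ_radius,
               length.out = nro + 1L)
    ozs <- seq(z_hinge - spec$organ_length / 2,
               z_hinge + spec$organ_length / 2, length.out = noz + 1L)
    oth <- 2 * pi * (seq_len(nco) - 1L) / nco
    onid <- function(iz, ir, ic) {
      ic <- (ic - 1L) %% nco + 1L
      o0 + ((iz - 1L) * (nro + 1L) + (ir - 1L)) * nco + ic
    }
    og <- expand.grid(ic = seq_len(nco), ir = seq_len(nro + 1L),
                      iz = seq_len(noz + 1L))
    oid <- onid(og$iz, og$ir, og$ic)
    oxyz <- cbind(ors[og$ir] * cos(oth[og$ic]) + spec$organ_offset[1L],
                  ors[og$ir] * sin(oth[og$ic]) + spec$organ_offset[2L],
                  ozs[og$iz])
    extra_ids <- c(extra_ids, oid[order(oid)])
    extra_coords <- rbind(extra_coords, oxyz[order(oid), ])
    organ_ids <- sort(oid)

    ol <- expand.grid(ic = seq_len(nco), ir = seq_len(nro),
                      iz = seq_len(noz))
    organ_hex <- cbind(onid(ol$iz, ol$ir, ol$ic),
                       onid(ol$iz, ol$ir + 1L, ol$ic),
                       onid(ol$iz, ol$ir + 1L, ol$ic + 1L),
                       onid(ol$iz, ol$ir, ol$ic + 1L),
                       onid(ol$iz + 1L, ol$ir, ol$ic),
                       onid(ol$iz + 1L, ol$ir + 1L, ol$ic),
                       onid(ol$iz + 1L, ol$ir + 1L, ol$ic + 1L),
                       onid(ol$iz + 1L, ol$ir, ol$ic + 1L))

    # tether: every other outer-ring node of the organ's lower end beams to
    # the nearest node of the lower bone-end corner ring (suspensory
    # attachment to one segment, as for mesentery-like structures)
    iz_low <- which.min(abs(zs - L1))
    ring_ids <- nid(iz_low, nrb + 1L, seq_len(nc))
    ring_xyz <- cbind(rs[nrb + 1L] * cos(th), rs[nrb + 1L] * sin(th),
                      zs[iz_low])
    teth_src <- onid(1L, nro + 1L, seq(1L, nco, by = 2L))
    src_xyz <- cbind(ors[nro + 1L] * cos(oth[seq(1L, nco, by = 2L)]) +
                       spec$organ_offset[1L],
                     ors[nro + 1L] * sin(oth[seq(1L, nco, by = 2L)]) +
                       spec$organ_offset[2L],
                     ozs[1L])
    nn <- knn_indices(src_xyz, ring_xyz, 1L)
    beams <- cbind(teth_src, ring_ids[nn[, 1L]])
  }

  # ---- assemble, pruning unreferenced grid nodes -------------------------
  all_ids <- c(ids, extra_ids)
  all_coords <- rbind(coords, extra_coords)
  used <- unique(c(as.vector(hex), as.vector(shells),
                   as.vector(organ_hex), as.vector(beams)))
  keep_nodes <- all_ids %in% used
  all_ids <- all_ids[keep_nodes]
  all_coords <- all_coords[keep_nodes, , drop = FALSE]

  solids <- list(conn = rbind(hex, organ_hex),
                 eid = seq_len(nrow(hex) + NROW(organ_hex)),
                 pid = c(solid_pid, rep(4L, NROW(organ_hex))))
  shells_blk <- list(conn = shells,
                     eid = nrow(solids$conn) + seq_len(nrow(shells)),
                     pid = shell_pid)
  beams_blk <- NULL
  if (!is.null(beams))
    beams_blk <- list(conn = beams,
                      eid = nrow(solids$conn) + nrow(shells) +
                        seq_len(nrow(beams)),
                      pid = rep(5L, nrow(beams)))
  part_names <- c("1" = "bone", "2" = "flesh", "3" = "skin",
                  "4" = "organ", "5" = "tether")
  if (!spec$organ) part_names <- part_names[1:3]
  mesh <- fe_mesh(all_ids, all_coords, solids = solids,
                  shells = shells_blk, beams = beams_blk,
                  part_names = part_names)

  # ---- armature and skinning weights -------------------------------------
  arm <- armature(pivots = rbind(c(0, 0, 0), c(0, 0, z_hinge)),
                  axes = rbind(c(1, 0, 0), c(1, 0, 0)),
                  angles = c(0, 0), parents = c(0L, 1L))
  z <- mesh$coords[, 3L]
  t_band <- pmin(1, pmax(0, (z - (z_hinge - spec$blend_band / 2)) /
                           spec$blend_band))
  w2 <- 3 * t_band^2 - 2 * t_band^3 # smoothstep
  # bone binds rigidly to its segment (no blending inside bone)
  bone_ids <- .part_node_ids(mesh, 1L)
  rigid <- mesh$node_ids %in% bone_ids
  w2[rigid] <- as.numeric(z[rigid] > z_hinge)
  weights <- cbind(1 - w2, w2)

  flesh_wall <- with(expand.grid(ic = seq_len(nc), iz = seq_len(nz)),
                     nid(iz, nrb + 1L, ic)[zs[iz] > L1 & zs[iz] < L1 + g])
  flesh_wall <- intersect(sort(flesh_wall), mesh$node_ids)

  list(mesh = mesh,
       parts = as.list(stats::setNames(as.integer(names(part_names)),
                                       part_names)),
       armature = arm, weights = weights,
       interface_ids = list(organ = intersect(organ_ids, mesh$node_ids),
                            flesh_wall = flesh_wall),
       spec = spec)
}

# All-quad cap over a disk bounded by a node ring (nc divisible by 4):
# the ring is split into 4 arcs forming the sides of an (m x m) transfinite
# patch; interior nodes are Coons-interpolated from the boundary.
.disk_patch <- function(nc, radius, th, z, first_id, ring_ids) {
  m <- nc %/% 4L
  ic_of <- function(i, j) { # boundary grid index -> ring position
    ic <- integer(length(i))
    ic[j == 0L] <- 1L + i[j == 0L]
    ic[i == m & j > 0L] <- m + 1L + j[i == m & j > 0L]
    ic[j == m & i < m] <- 2L * m + 1L + (m - i[j == m & i < m])
    ic[i == 0L & j > 0L & j < m] <- 3L * m + 1L +
      (m - j[i == 0L & j > 0L & j < m])
    (ic - 1L) %% nc + 1L
  }
  P <- array(NA_real_, c(m + 1L, m + 1L, 2L))
  N <- matrix(NA_integer_, m + 1L, m + 1L)
  for (i in 0:m) for (j in 0:m) {
    if (i %in% c(0L, m) || j %in% c(0L, m)) {
      ic <- ic_of(i, j)
      P[i + 1L, j + 1L, ] <- radius * c(cos(th[ic]), sin(th[ic]))
      N[i + 1L, j + 1L] <- ring_ids[ic]
    }
  }
  next_id <- first_id
  new_ids <- integer(0); new_xy <- NULL
  for (i in 1:(m - 1L)) for (j in 1:(m - 1L)) {
    u <- i / m; v <- j / m
    p <- (1 - v) * P[i + 1L, 1L, ] + v * P[i + 1L, m + 1L, ] +
      (1 - u) * P[1L, j + 1L, ] + u * P[m + 1L, j + 1L, ] -
      ((1 - u) * (1 - v) * P[1L, 1L, ] + u * (1 - v) * P[m + 1L, 1L, ] +
         (1 - u) * v * P[1L, m + 1L, ] + u * v * P[m + 1L, m + 1L, ])
    P[i + 1L, j + 1L, ] <- p
    N[i + 1L, j + 1L] <- next_id
    new_ids <- c(new_ids, next_id)
    new_xy <- rbind(new_xy, p)
    next_id <- next_id + 1L
  }
  qg <- expand.grid(i = 0:(m - 1L), j = 0:(m - 1L))
  quads <- cbind(N[cbind(qg$i + 1L, qg$j + 1L)],
                 N[cbind(qg$i + 2L, qg$j + 1L)],
                 N[cbind(qg$i + 2L, qg$j + 2L)],
                 N[cbind(qg$i + 1L, qg$j + 2L)])
  # the 4 cells at the arc junctions each cover a 165-degree boundary
  # angle in one quad corner; split them along the diagonal through the
  # ring corner node into two well-shaped triangles
  corner_cell <- list(c(0L, 0L, 1L), c(m - 1L, 0L, 2L),
                      c(m - 1L, m - 1L, 3L), c(0L, m - 1L, 4L))
  tri <- NULL; drop <- integer(0)
  for (cc in corner_cell) {
    row <- which(qg$i == cc[1L] & qg$j == cc[2L])
    q4 <- quads[row, ]
    if (cc[3L] %in% c(1L, 3L)) # ring corner on the a-c diagonal
      tri <- rbind(tri, q4[c(1L, 2L, 3L, 3L)], q4[c(1L, 3L, 4L, 4L)])
    else # ring corner on the b-d diagonal
      tri <- rbind(tri, q4[c(1L, 2L, 4L, 4L)], q4[c(2L, 3L, 4L, 4L)])
    drop <- c(drop, row)
  }
  quads <- rbind(quads[-drop, , drop = FALSE], tri)
  list(ids = new_ids, coords = cbind(new_xy, z), quads = quads,
       next_id = next_id)
}

#' Set the hinge angle of a limb armature
#' @param arm the 2-joint [armature()] from [generate_limb()].
#' @param angle hinge angle in degrees.
#' @return the armature with the hinge joint set.
#' @export
bend_armature <- function(arm, angle) {
  arm$angles[length(arm$angles)] <- angle
  arm
}

#' Count nodes penetrating a closed surface
#'
#' Ray-parity point-in-polyhedron test: a point is inside the closed
#' surface when a ray from it crosses the (triangulated) faces an odd
#' number of times. Three fixed, axis-skew ray directions are voted
#' (majority) so edge-grazing rays cannot flip the answer silently. Counts
#' points strictly *outside* (default: e.g. organ nodes escaping the skin)
#' or strictly *inside* (e.g. organ nodes swallowed by the skeleton:
#' "inside the wrong part").
#'
#' @param points q x 3 coordinates to classify (e.g. posed inner-surface
#'   nodes).
#' @param surface a `surface_set` for the outer surface; must be closed
#'   (every triangulated edge shared by exactly two triangles), else an
#'   error.
#' @param surface_coords matrix of surface node positions aligned with
#'   `surface$node_ids`.
#' @param mode `"outside"` or `"inside"`.
#' @return integer count, with attribute `"which"` giving the offending
#'   row indices of `points`.
#' @export
count_penetrations <- function(points, surface, surface_coords,
                               mode = c("outside", "inside")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  v <- as.matrix(surface_coords)
  if (nrow(v) != length(surface$node_ids))
    stop("surface_coords do not align with the surface node list")
  tri <- .triangulate_faces(surface, v)
  .check_closed(tri$idx)

  dirs <- rbind(c(0.7237469, 0.4912501, 0.4845316),
                c(-0.3712157, 0.8526327, 0.3672214),
                c(0.1978155, -0.5286335, 0.8254513))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  votes <- matrix(0L, nrow(points), nrow(dirs))
  for (r in seq_len(nrow(dirs)))
    votes[, r] <- .ray_parity(points, tri$v0, tri$e1, tri$e2, dirs[r, ])
  inside <- rowSums(votes) >= 2L
  hit <- if (mode == "outside") which(!inside) else which(inside)
  structure(length(hit), which = hit)
}

.triangulate_faces <- function(surface, v) {
  f <- surface$faces
  vert <- match(f, surface$node_ids)
  dim(vert) <- dim(f)
  quad <- vert[, 3L] != vert[, 4L]
  idx <- rbind(vert[, c(1L, 2L, 3L)],
               vert[quad, c(1L, 3L, 4L), drop = FALSE])
  list(idx = idx, v0 = v[idx[, 1L], , drop = FALSE],
       e1 = v[idx[, 2L], , drop = FALSE] - v[idx[, 1L], , drop = FALSE],
       e2 = v[idx[, 3L], , drop = FALSE] - v[idx[, 1L], , drop = FALSE])
}

.check_closed <- function(idx) {
  edges <- rbind(idx[, 1:2], idx[, 2:3], idx[, c(3L, 1L)])
  key <- paste(pmin(edges[, 1L], edges[, 2L]),
               pmax(edges[, 1L], edges[, 2L]))
  tab <- table(key)
  if (any(tab != 2L))
    stop("outer surface is not closed (", sum(tab != 2L),
         " boundary/non-manifold edge(s))")
  invisible(TRUE)
}

# parity of ray crossings per point for one direction (Moller-Trumbore,
# vectorised over points, looped over triangles)
.ray_parity <- function(points, v0, e1, e2, d) {
  q <- nrow(points)
  crossings <- integer(q)
  h <- .row_cross(matrix(d, nrow(v0), 3L, byrow = TRUE), e2)
  a <- rowSums(e1 * h)
  eps <- 1e-12
  for (tr in seq_len(nrow(v0))) {
    if (abs(a[tr]) < eps) next
    s <- sweep(points, 2L, v0[tr, ])
    u <- (s %*% h[tr, ]) / a[tr]
    qv <- cbind(s[, 2L] * e1[tr, 3L] - s[, 3L] * e1[tr, 2L],
                s[, 3L] * e1[tr, 1L] - s[, 1L] * e1[tr, 3L],
                s[, 1L] * e1[tr, 2L] - s[, 2L] * e1[tr, 1L])
    vv <- (qv %*% d) / a[tr]
    tt <- (qv %*% e2[tr, ]) / a[tr]
    hitr <- u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1 & tt > eps
    crossings <- crossings + as.integer(hitr)
  }
  as.integer(crossings %% 2L)
}
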