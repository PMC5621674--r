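# Structured, graded triangulation of the axisymmetric section.
#
# The section r in [0, r_domain], z in [-(t_c + t_tr), 0] is covered by a
# tensor grid with mesh lines placed exactly at the pipette inner radius,
# the pipette outer radius, and the compact/trabecular interface.  Cells are
# graded toward the pipette edge annulus and the loaded surface, where
# stress gradients concentrate, then split into 6-node quadratic triangles.

# n geometric intervals from a to b; spacing_{k+1} = ratio * spacing_k
grade_seg <- function(a, b, n, ratio = 1) {
  s <- ratio^(seq_len(n) - 1L)
  s <- s / sum(s)
  a + (b - a) * c(0, cumsum(s))
}

mesh_breaks <- function(geom, refine = 1) {
  nA <- max(4L, round(10 * refine))  # axis to pipette inner radius
  nB <- max(2L, round(4 * refine))   # contact annulus
  nC <- max(4L, round(12 * refine))  # annulus to fixed outer edge
  nT <- max(3L, round(9 * refine))   # compact layer
  nD <- max(4L, round(10 * refine))  # trabecular layer
  nF <- max(1L, round(2.4 * refine)) # fillet-relief rings
  r_o <- geom$r_i + geom$wall
  f <- min(geom$fillet, geom$wall / 4)
  rann <- if (f > 0) {
    c(grade_seg(geom$r_i, geom$r_i + f, nF, ratio = 1)[-1L],
      grade_seg(geom$r_i + f, r_o - f, nB, ratio = 1)[-1L],
      grade_seg(r_o - f, r_o, nF, ratio = 1)[-1L])
  } else {
    grade_seg(geom$r_i, r_o, nB, ratio = 1)[-1L]
  }
  rb <- c(grade_seg(0, geom$r_i, nA, ratio = 0.85), rann,
          grade_seg(r_o, geom$r_domain, nC, ratio = 1.35)[-1L])
  tt <- geom$t_c + geom$t_tr
  zb <- c(grade_seg(-tt, -geom$t_c, nD, ratio = 0.75),
          grade_seg(-geom$t_c, 0, nT, ratio = 0.88)[-1L])
  list(rb = rb, zb = zb)
}

# Build the T6 mesh plus all bookkeeping the solver needs.
pa_mesh <- function(geom, refine = 1) {
  br <- mesh_breaks(geom, refine)
  rb <- br$rb
  zb <- br$zb
  nr <- length(rb) - 1L
  nz <- length(zb) - 1L
  ncorner_r <- nr + 1L
  ncorner_z <- nz + 1L
  idx <- matrix(seq_len(ncorner_r * ncorner_z), ncorner_r, ncorner_z)
  corners <- cbind(rep(rb, times = ncorner_z), rep(zb, each = ncorner_r))

  # two CCW triangles per cell, diagonal from lower-left to upper-right
  i <- rep(seq_len(nr), times = nz)
  j <- rep(seq_len(nz), each = nr)
  n00 <- idx[cbind(i, j)]
  n10 <- idx[cbind(i + 1L, j)]
  n01 <- idx[cbind(i, j + 1L)]
  n11 <- idx[cbind(i + 1L, j + 1L)]
  tri3 <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))

  # unique midside nodes per edge
  ed <- rbind(tri3[, c(1L, 2L)], tri3[, c(2L, 3L)], tri3[, c(3L, 1L)])
  ed <- cbind(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  key <- ed[, 1L] + ed[, 2L] * (nrow(corners) + 1)
  ukey <- unique(key)
  eid <- match(key, ukey)
  uidx <- match(ukey, key)
  mids <- (corners[ed[uidx, 1L], , drop = FALSE] +
           corners[ed[uidx, 2L], , drop = FALSE]) / 2
  ntri <- nrow(tri3)
  midnode <- matrix(nrow(corners) + eid, ntri, 3L)
  tri6 <- cbind(tri3, midnode)
  nodes <- rbind(corners, mids)

  tol <- 1e-9
  # pressure dofs live at corner nodes (continuous linear field)
  pmap <- integer(nrow(nodes))
  pmap[seq_len(nrow(corners))] <- seq_len(nrow(corners))

  # subdomain assignment by centroid depth
  zc <- (corners[tri3[, 1L], 2L] + corners[tri3[, 2L], 2L] +
         corners[tri3[, 3L], 2L]) / 3
  trabecular <- zc < -geom$t_c + tol

  # all top-surface edges (low-r corner, midside, high-r corner)
  all_cells <- seq_len(nr)
  lo <- idx[cbind(all_cells, ncorner_z)]
  hi <- idx[cbind(all_cells + 1L, ncorner_z)]
  ekey <- pmin(lo, hi) + pmax(lo, hi) * (nrow(corners) + 1)
  mid <- nrow(corners) + match(ekey, ukey)
  top_edges <- cbind(lo, mid, hi)
  # loaded edges: free surface inside the pipette lumen, r <= r_i
  loaded <- rb[-1L] <= geom$r_i + tol
  bele <- if (any(loaded)) top_edges[loaded, , drop = FALSE] else NULL

  # constraint sets
  r_all <- nodes[, 1L]
  z_all <- nodes[, 2L]
  on_axis <- r_all < tol
  on_outer <- r_all > geom$r_domain - tol
  # the pipette tip carries an edge fillet on both wall corners: flat contact
  # (and hence the roller constraint) spans the annulus reduced by the fillet
  # radius at each edge; the relief rings stay free, which regularizes the
  # contact-edge corner the fillet smooths in reality
  f <- min(geom$fillet, geom$wall / 4)
  on_roller <- z_all > -tol & r_all >= geom$r_i + f - tol &
    r_all <= geom$r_i + geom$wall - f + tol
  fixed_u <- unique(c(
    2L * which(on_axis) - 1L,            # u_r = 0 on the axis
    2L * which(on_roller),               # u_z = 0 under the pipette tip
    2L * which(on_outer) - 1L,           # outer edge fully fixed
    2L * which(on_outer)))
  ndof <- 2L * nrow(nodes) + nrow(corners)
  free <- setdiff(seq_len(ndof), sort(fixed_u))

  apex_node <- which(on_axis & z_all > -tol)[1L]

  list(nodes = nodes, tri = tri6, pmap = pmap, np = nrow(corners),
       bele = bele, top_edges = top_edges, free = free, ndof = ndof,
       apex_node = apex_node, trabecular = trabecular, rb = rb, zb = zb,
       n_elements = ntri)
}

# locate the element and barycentric coordinates of reference point (r, z)
locate_point <- function(mesh, r, z) {
  rb <- mesh$rb
  zb <- mesh$zb
  nr <- length(rb) - 1L
  nz <- length(zb) - 1L
  if (r < rb[1L] - 1e-9 || r > rb[nr + 1L] + 1e-9 ||
      z < zb[1L] - 1e-9 || z > zb[nz + 1L] + 1e-9)
    pa_stop(sprintf("query point (%.4g, %.4g) lies outside the meshed domain", r, z),
            "pamech_out_of_domain")
  i <- min(max(findInterval(r, rb, rightmost.closed = TRUE), 1L), nr)
  j <- min(max(findInterval(z, zb, rightmost.closed = TRUE), 1L), nz)
  cell <- (j - 1L) * nr + i
  # local cell coordinates in [0,1]^2; diagonal runs lower-left -> upper-right
  s <- (r - rb[i]) / (rb[i + 1L] - rb[i])
  t <- (z - zb[j]) / (zb[j + 1L] - zb[j])
  ntri_half <- nr * nz
  if (t <= s + 1e-12) {
    # lower triangle (n00, n10, n11): l1 at n00, l2 at n10, l3 at n11
    elem <- cell
    l2 <- s - t
    l3 <- t
    l1 <- 1 - l2 - l3
  } else {
    # upper triangle (n00, n11, n01)
    elem <- ntri_half + cell
    l2 <- s
    l3 <- t - s
    l1 <- 1 - l2 - l3
  }
  list(elem = elem, l1 = l1, l2 = l2)
}
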