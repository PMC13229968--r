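# Forward-kinematic 3-D reconstruction and simulation-based traits.
#
# Conventions (used consistently by generator and traits): right-handed
# frames with z up; an organ frame's z axis is its growth direction. Angle
# triples are applied as intrinsic rotations pitch -> yaw -> roll,
# M = Ry(pitch) %*% Rz(yaw) %*% Rx(roll), so a zero-angle internode of
# length L runs from its base to (0, 0, L). The phyllotactic angle
# accumulates azimuth (a local z rotation) along each shoot. Petiole
# curvature bends the petiole as a circular arc in its pitch plane,
# discretized in 5 segments, with the raw stored value read as bend rate in
# degrees per metre. Leaf laminae are squares of side scale * sqrt(A0) lying
# in the local x-y plane (normal = local z).

.d2r <- function(a) a * pi / 180

.rx <- function(a) {
  a <- .d2r(a); c1 <- cos(a); s1 <- sin(a)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
}
.ry <- function(a) {
  a <- .d2r(a); c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
}
.rz <- function(a) {
  a <- .d2r(a); c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}
.rot_pyr <- function(pitch, yaw, roll) .ry(pitch) %*% .rz(yaw) %*% .rx(roll)

# Structural leaflet azimuths by leaf count: a lone leaf points along the
# petiole, two opposite unifoliate leaves sit at 0/180, trifoliate leaflets
# at 0/+60/-60 with lateral leaflets shrunk by the petiole's leaflet_scale.
.leaf_azimuths <- function(n) switch(n, c(0), c(0, 180), c(0, 60, -60))

#' Construct a 3-D geometry container
#'
#' Usually produced by [reconstruct_geometry()]; exposed so trait functions
#' can be exercised on hand-built geometries.
#'
#' @param segments Matrix with columns `x0,y0,z0,x1,y1,z1` (one row per
#'   internode/petiole segment), or `NULL`.
#' @param leaves List of leaves, each a list with `center` (length-3),
#'   `normal` (unit length-3), `area` (m^2) and `corners` (4 x 3 matrix).
#' @param base Length-3 plant base position.
#' @return Object of class `pa_geometry`.
#' @export
geometry3d <- function(segments = NULL, leaves = list(), base = c(0, 0, 0)) {
  structure(list(segments = segments, leaves = leaves, base = as.numeric(base)),
            class = "pa_geometry")
}

#' Reconstruct 3-D geometry from a plant architecture
#'
#' Composes the rotation chain plant base -> shoot base -> per-phytomer
#' internode (pitch plus cumulative phyllotactic azimuth) -> petiole (pitch
#' plus circular-arc curvature) -> leaf (pitch, yaw, roll), accumulating
#' segment vectors scaled by organ lengths. Leaf area is
#' `scale^2 * unit_leaf_area` (lateral trifoliate leaflets additionally
#' scaled by the petiole's `leaflet_scale`).
#'
#' @param plant A valid [plant_architecture()].
#' @param unit_leaf_area Area of the unit leaf prototype at scale 1, m^2.
#' @param azimuth_offset_deg Extra rigid rotation of the whole plant about
#'   the vertical axis, degrees (useful for invariance checks and
#'   multi-view-style layouts).
#' @param arc_segments Number of straight segments per curved petiole.
#' @return A [geometry3d()] object.
#' @export
reconstruct_geometry <- function(plant, unit_leaf_area = 1.0,
                                 azimuth_offset_deg = 0, arc_segments = 5L) {
  base_frame <- .rz(azimuth_offset_deg) %*%
    .rot_pyr(plant$base_rotation[1], plant$base_rotation[2], plant$base_rotation[3])
  base_pos <- plant$base_position

  segs <- vector("list", 256); n_seg <- 0L
  push_seg <- function(p0, p1) {
    n_seg <<- n_seg + 1L
    if (n_seg > length(segs)) length(segs) <<- 2L * n_seg
    segs[[n_seg]] <<- c(p0, p1)
  }
  leaves_out <- vector("list", 256); n_leaf <- 0L
  push_leaf <- function(lf) {
    n_leaf <<- n_leaf + 1L
    if (n_leaf > length(leaves_out)) length(leaves_out) <<- 2L * n_leaf
    leaves_out[[n_leaf]] <<- lf
  }

  shoots <- plant$shoots
  ids <- vapply(shoots, function(s) s$shoot_id, integer(1))
  parent <- vapply(shoots, function(s) s$parent_shoot_id, integer(1))
  pnode <- vapply(shoots, function(s) s$parent_node_index, integer(1))

  emit_leaf <- function(attach_pos, attach_frame, lf, azimuth, scale_mult) {
    frame <- attach_frame %*% .rz(azimuth) %*% .rot_pyr(lf$pitch, lf$yaw, lf$roll)
    s_eff <- lf$scale * scale_mult
    side <- s_eff * sqrt(unit_leaf_area)
    ex <- frame[, 1]; ey <- frame[, 2]; ez <- frame[, 3]
    center <- attach_pos + ex * (side / 2)
    h <- side / 2
    corners <- rbind(center - ex * h - ey * h, center + ex * h - ey * h,
                     center + ex * h + ey * h, center - ex * h + ey * h)
    push_leaf(list(center = center, normal = ez, area = s_eff^2 * unit_leaf_area,
                   corners = corners))
  }

  emit_shoot <- function(si, attach_pos, attach_frame) {
    s <- shoots[[si]]
    frame <- attach_frame %*% .rot_pyr(s$base_pitch, s$base_yaw, s$base_roll)
    pos <- attach_pos
    for (k in seq_along(s$phytomers)) {
      ph <- s$phytomers[[k]]
      frame <- frame %*% .rz(ph$internode$phyllotactic_angle) %*%
        .ry(ph$internode$pitch)
      top <- pos + frame[, 3] * ph$internode$length
      push_seg(pos, top)
      node_pos <- top

      pet <- ph$petiole
      pframe <- frame %*% .ry(pet$pitch)
      bend_total <- pet$curvature * pet$length
      nseg <- max(1L, arc_segments)
      ppos <- node_pos
      for (a in seq_len(nseg)) {
        pframe <- pframe %*% .ry(bend_total / nseg)
        pnext <- ppos + pframe[, 3] * (pet$length / nseg)
        push_seg(ppos, pnext)
        ppos <- pnext
      }

      nl <- length(ph$leaves)
      az <- .leaf_azimuths(nl)
      for (l in seq_len(nl)) {
        mult <- if (!is.null(pet$leaflet_scale) && l > 1) pet$leaflet_scale else 1
        emit_leaf(ppos, pframe, ph$leaves[[l]], az[l], mult)
      }

      kids <- which(parent == s$shoot_id & pnode == (k - 1L))
      for (ci in kids) emit_shoot(ci, node_pos, frame)
      pos <- top
    }
  }

  root <- which(parent == -1L)
  if (length(root) == 1) emit_shoot(root, base_pos, base_frame)

  seg_mat <- if (n_seg > 0) {
    m <- do.call(rbind, segs[seq_len(n_seg)])
    colnames(m) <- c("x0", "y0", "z0", "x1", "y1", "z1")
    m
  } else NULL
  geometry3d(segments = seg_mat, leaves = leaves_out[seq_len(n_leaf)],
             base = base_pos)
}

.all_points <- function(geom) {
  pts <- NULL
  if (!is.null(geom$segments) && nrow(geom$segments) > 0)
    pts <- rbind(geom$segments[, 1:3, drop = FALSE],
                 geom$segments[, 4:6, drop = FALSE])
  if (length(geom$leaves) > 0)
    pts <- rbind(pts, do.call(rbind, lapply(geom$leaves, `[[`, "corners")))
  pts
}

#' Plant height
#'
#' Highest point of any organ above the plant base (max z minus base z).
#' Empty geometry yields 0.
#'
#' @param geom A [geometry3d()] object.
#' @return Height in metres.
#' @export
plant_height <- function(geom) {
  pts <- .all_points(geom)
  if (is.null(pts) || nrow(pts) == 0) return(0)
  max(pts[, 3]) - geom$base[3]
}

#' Total leaf area
#'
#' @param geom A [geometry3d()] object.
#' @return Sum of leaf areas, m^2.
#' @export
total_leaf_area <- function(geom) {
  if (length(geom$leaves) == 0) return(0)
  sum(vapply(geom$leaves, `[[`, numeric(1), "area"))
}

#' Leaf inclination distribution
#'
#' Inclination of each leaf is the angle between its surface normal and the
#' vertical, folded to `[0, 90]` degrees; the histogram is normalized to unit
#' mass over equal-width bins spanning 0--90 degrees.
#'
#' @param geom A [geometry3d()] with at least one leaf.
#' @param n_bins Number of bins (default 10 bins of 9 degrees).
#' @return Named numeric vector of bin probability masses.
#' @export
leaf_inclination_distribution <- function(geom, n_bins = 10L) {
  if (length(geom$leaves) == 0)
    stop("geometry has no leaves", call. = FALSE)
  nz <- vapply(geom$leaves, function(l) abs(l$normal[3]), numeric(1))
  incl <- acos(pmin(1, pmax(-1, nz))) * 180 / pi
  breaks <- seq(0, 90, length.out = n_bins + 1L)
  idx <- pmin(n_bins, findInterval(incl, breaks, rightmost.closed = TRUE))
  idx <- pmax(1L, idx)
  counts <- tabulate(idx, nbins = n_bins)
  masses <- counts / sum(counts)
  names(masses) <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  masses
}

#' Count organs in a token sequence
#'
#' Tallies organ tokens directly: shoots are organ-code-0 tokens, phytomers
#' are internode tokens (code 1) and leaves are leaf-slot tokens (codes
#' 3--5).
#'
#' @param seq A [token_sequence()] or integer vector of token IDs.
#' @return List with `n_shoots`, `n_phytomers`, `n_leaves`.
#' @export
count_organs <- function(seq) {
  ids <- as.integer(unclass(seq))
  organ <- ids[ids < .N_ORGAN]
  code <- organ %% 6L
  list(n_shoots = sum(code == 0L),
       n_phytomers = sum(code == 1L),
       n_leaves = sum(code >= 3L))
}

# Point-in-convex-quad test for a matrix of points (n x 2) against 4 ordered
# corners (4 x 2). Degenerate (near-zero-area) quads match nothing.
.in_quad <- function(pts, quad) {
  # polygon orientation from its own vertices (ordered convex quad)
  o <- sign((quad[2, 1] - quad[1, 1]) * (quad[3, 2] - quad[2, 2]) -
              (quad[2, 2] - quad[1, 2]) * (quad[3, 1] - quad[2, 1]))
  if (o == 0) return(rep(FALSE, nrow(pts)))
  inside <- rep(TRUE, nrow(pts))
  for (e in 1:4) {
    a <- quad[e, ]; b <- quad[if (e == 4) 1 else e + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (cr * o >= -1e-12)
  }
  inside
}

#' Image-window metadata from geometry
#'
#' Width is the larger horizontal side of the plant's bounding box, height is
#' [plant_height()], and the vegetation fraction is the proportion of cells
#' of a top-view orthographic rasterization of the leaf laminae (over a
#' square window of side `window_m` centered on the plant base) that are
#' covered.
#'
#' @param geom A [geometry3d()] object.
#' @param window_m Side of the square image window, metres (> 0).
#' @param resolution Raster grid resolution per side (default 256).
#' @return A [plant_metadata()] object.
#' @export
bounding_metadata <- function(geom, window_m = 1.0, resolution = 256L) {
  if (!is.numeric(window_m) || window_m <= 0)
    stop("window_m must be > 0", call. = FALSE)
  pts <- .all_points(geom)
  width <- if (is.null(pts) || nrow(pts) == 0) 0 else
    max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  height <- plant_height(geom)

  frac <- 0
  if (length(geom$leaves) > 0) {
    res <- as.integer(resolution)
    cell <- window_m / res
    x0 <- geom$base[1] - window_m / 2
    y0 <- geom$base[2] - window_m / 2
    centers <- (seq_len(res) - 0.5) * cell
    occupied <- matrix(FALSE, res, res)
    for (lf in geom$leaves) {
      quad <- lf$corners[, 1:2, drop = FALSE]
      quad[, 1] <- quad[, 1] - x0
      quad[, 2] <- quad[, 2] - y0
      # degenerate top-view projection (near-vertical leaf) covers ~nothing
      a2 <- abs((quad[2, 1] - quad[1, 1]) * (quad[4, 2] - quad[1, 2]) -
                  (quad[2, 2] - quad[1, 2]) * (quad[4, 1] - quad[1, 1]))
      if (a2 < (cell * 1e-6)^2) next
      ix <- which(centers >= min(quad[, 1]) - cell & centers <= max(quad[, 1]) + cell)
      iy <- which(centers >= min(quad[, 2]) - cell & centers <= max(quad[, 2]) + cell)
      if (length(ix) == 0 || length(iy) == 0) next
      grid_pts <- cbind(rep(centers[ix], times = length(iy)),
                        rep(centers[iy], each = length(ix)))
      hit <- .in_quad(grid_pts, quad)
      if (any(hit)) {
        sub <- matrix(hit, nrow = length(ix))
        occupied[ix, iy] <- occupied[ix, iy] | sub
      }
    }
    frac <- sum(occupied) / (res * res)
  }
  plant_metadata(width_m = width, height_m = height, vegetation_fraction = frac)
}

#' Simulation-based trait report for a plant
#'
#' Reconstructs the geometry and derives the bulk traits that require the 3-D
#' model: plant height, leaf count and total area, the leaf inclination
#' histogram, and direct organ tallies.
#'
#' @param plant A valid [plant_architecture()].
#' @param n_bins Number of inclination bins.
#' @param unit_leaf_area Area of the unit leaf prototype at scale 1, m^2.
#' @return List with `height_m`, `leaf_count`, `total_leaf_area_m2`,
#'   `inclination_histogram`, `n_shoots`, `n_phytomers`.
#' @export
plant_traits <- function(plant, n_bins = 10L, unit_leaf_area = 1.0) {
  geom <- reconstruct_geometry(plant, unit_leaf_area = unit_leaf_area)
  n_shoots <- length(plant$shoots)
  n_phyt <- sum(vapply(plant$shoots, function(s) length(s$phytomers), integer(1)))
  list(height_m = plant_height(geom),
       leaf_count = length(geom$leaves),
       total_leaf_area_m2 = total_leaf_area(geom),
       inclination_histogram = if (length(geom$leaves) > 0)
         leaf_inclination_distribution(geom, n_bins) else NULL,
       n_shoots = n_shoots,
       n_phytomers = n_phyt)
}
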