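# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive all-pairs / explicit set arithmetic so they share
# no code path with the package implementations they check.

# random binary mask
rand_mask <- function(dims, p = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(prod(dims)) < p, dims)
}

# Dice by explicit index-set arithmetic
bf_dice <- function(a, b) {
  ia <- which(a)
  ib <- which(b)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# voxel-centre coordinates (micrometres) of all voxels, n x 3
vox_coords <- function(dims, vs) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  sweep(co - 0.5, 2, vs, `*`)
}

# all-pairs exact Euclidean distance map to the reference set
# (micrometres); squared distances formed from per-coordinate differences
# so no cancellation occurs
bf_edt <- function(ref, vs) {
  dims <- dim(ref)
  pts <- vox_coords(dims, vs)[which(ref), , drop = FALSE]
  all_pts <- vox_coords(dims, vs)
  out <- numeric(nrow(all_pts))
  block <- 4000L
  for (s in seq(1, nrow(all_pts), by = block)) {
    e <- min(s + block - 1L, nrow(all_pts))
    blk <- all_pts[s:e, , drop = FALSE]
    d2 <- outer(blk[, 1], pts[, 1], `-`)^2 +
      outer(blk[, 2], pts[, 2], `-`)^2 +
      outer(blk[, 3], pts[, 3], `-`)^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  array(out, dims)
}

# dilation/erosion/closing with an explicit Euclidean-ball offset list
bf_ball_offsets <- function(radius_um, vs) {
  rv <- floor(radius_um / vs)
  off <- as.matrix(expand.grid(x = -rv[1]:rv[1], y = -rv[2]:rv[2],
                               z = -rv[3]:rv[3]))
  off[colSums((t(off) * vs)^2) <= radius_um^2, , drop = FALSE]
}

bf_dilate <- function(mask, radius_um, vs) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  idx <- which(mask)
  co <- arrayInd(idx, dims)
  for (o in seq_len(nrow(off <- bf_ball_offsets(radius_um, vs)))) {
    sh <- sweep(co, 2, off[o, ], `+`)
    ok <- sh[, 1] >= 1 & sh[, 1] <= dims[1] &
      sh[, 2] >= 1 & sh[, 2] <= dims[2] &
      sh[, 3] >= 1 & sh[, 3] <= dims[3]
    out[sh[ok, , drop = FALSE]] <- TRUE
  }
  out
}

bf_erode <- function(mask, radius_um, vs) {
  dims <- dim(mask)
  off <- bf_ball_offsets(radius_um, vs)
  idx <- which(mask)
  co <- arrayInd(idx, dims)
  keep <- rep(TRUE, length(idx))
  for (o in seq_len(nrow(off))) {
    sh <- sweep(co, 2, off[o, ], `+`)
    inside <- sh[, 1] >= 1 & sh[, 1] <= dims[1] &
      sh[, 2] >= 1 & sh[, 2] <= dims[2] &
      sh[, 3] >= 1 & sh[, 3] <= dims[3]
    # domain-restricted morphology: offsets falling outside the grid do
    # not disqualify (outside is "don't know", not background)
    ok <- !inside
    ok[inside] <- mask[sh[inside, , drop = FALSE]]
    keep <- keep & ok
  }
  out <- array(FALSE, dims)
  out[idx[keep]] <- TRUE
  out
}

# true Euclidean closing: evaluated on a padded grid and cropped, so no
# structuring-element placement is clipped for voxels of the original grid
bf_close <- function(mask, radius_um, vs) {
  pad <- ceiling(radius_um / vs) + 1
  d <- dim(mask)
  big <- array(FALSE, d + 2 * pad)
  idx <- lapply(1:3, function(a) seq(pad[a] + 1, pad[a] + d[a]))
  big[idx[[1]], idx[[2]], idx[[3]]] <- mask
  clo <- bf_erode(bf_dilate(big, radius_um, vs), radius_um, vs)
  clo[idx[[1]], idx[[2]], idx[[3]]]
}

# local thickness by the maximal-inscribed-sphere definition, computed with
# naive pairwise distances; mirrors the half-voxel-edge radius convention
bf_thickness <- function(mask, vs) {
  dims <- dim(mask)
  hv <- 0.5 * min(vs)
  all_pts <- vox_coords(dims, vs)
  mpts <- all_pts[which(mask), , drop = FALSE]
  bpts <- all_pts[which(!mask), , drop = FALSE]
  if (nrow(bpts) == 0) stop("oracle needs background voxels")
  pdist2 <- function(A, B) {
    outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2 +
      outer(A[, 3], B[, 3], `-`)^2
  }
  rad <- sqrt(apply(pdist2(mpts, bpts), 1, min)) # coverage radius
  dmm <- sqrt(pdist2(mpts, mpts))
  th <- vapply(seq_len(nrow(mpts)), function(i) {
    covered <- dmm[i, ] < rad # sphere stops at the first background centre
    2 * (max(rad[covered]) - hv)
  }, 0)
  out <- array(0, dims)
  out[which(mask)] <- th
  out
}

# brute-force centre-in-sphere voxelisation count
bf_sphere_count <- function(dims, vs, centre, radius) {
  pts <- vox_coords(dims, vs)
  sum(colSums((t(pts) - centre)^2) <= radius^2)
}

# small, fast phantom spec used across tests; component lists override the
# fixture defaults key-by-key
small_spec <- function(seed = 1, shell = list(), trabeculae = list(),
                       vessels = list(), metastases = list(),
                       render = list(), grid_shape = c(40, 40, 40),
                       voxel_size_um = 3.5) {
  phantom_spec(grid_shape = grid_shape, voxel_size_um = voxel_size_um,
               shell = utils::modifyList(
                 list(outer_radius_um = 56, wall_um = 10.5, taper = 0.12),
                 shell),
               trabeculae = utils::modifyList(
                 list(n_rods = 50, rod_radius_um = 6), trabeculae),
               vessels = utils::modifyList(
                 list(n_branches = 4, radius_range_um = c(6, 10),
                      min_branch_length_um = 100), vessels),
               metastases = utils::modifyList(
                 list(n_lesions = 1, semi_axes_range_um = c(28, 38)),
                 metastases),
               render = render,
               seed = seed)
}

# cohort spec mirroring the second-time-point treatment design: four groups
# of seven samples, one carrying a vessel-radius shrink near lesions
t2_cohort_spec <- function(factor_c = 0.6, seed = 1) {
  cohort_spec(groups = list(
    list(label = "P", n = 7, timepoint = "T2"),
    list(label = "B", n = 7, timepoint = "T2"),
    list(label = "V", n = 7, timepoint = "T2"),
    list(label = "C", n = 7, timepoint = "T2", radius_factor = factor_c,
         effect_distance_um = 700)),
    seed = seed)
}
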