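# Morphometry: TV contour, compartment volumes, distance transform, VMI,
# local thickness and the VOI restriction, each against independent
# brute-force oracles on small instances.

test_that("TV mask of a solid block is exactly the block", {
  lab <- array(0L, c(24, 24, 24))
  lab[8:17, 8:17, 8:17] <- 1L
  labels <- label_volume(lab, 1)
  tv <- total_volume_mask(labels, closing_radius_um = 10)
  expect_identical(which(tv), which(lab == 1L))
  expect_identical(sum(tv), 1000L)
})

test_that("a hollow closed shell contributes its cavity to TV", {
  dims <- c(26, 26, 26)
  shell <- voxelize_sphere(dims, 1, c(13, 13, 13), 9) &
    !voxelize_sphere(dims, 1, c(13, 13, 13), 6)
  lab <- array(0L, dims); lab[shell] <- 1L
  labels <- label_volume(lab, 1)
  tv <- total_volume_mask(labels, closing_radius_um = 2)
  # the enclosed cavity must be counted as interior
  cavity <- voxelize_sphere(dims, 1, c(13, 13, 13), 5)
  expect_true(all(tv[cavity]))
  expect_true(all(tv[shell]))
})

test_that("distant blocks are not bridged by the TV closing", {
  lab <- array(0L, c(30, 14, 14))
  lab[2:7, 4:9, 4:9] <- 1L
  lab[22:27, 4:9, 4:9] <- 1L
  labels <- label_volume(lab, 1)
  tv <- total_volume_mask(labels, closing_radius_um = 3)
  oracle <- bf_close(lab == 1L, 3, c(1, 1, 1))
  expect_identical(which(tv), which(oracle)) # no cavities here: close only
  gap <- tv[10:19, , ]
  expect_false(any(gap))
})

test_that("compartment volumes are voxel counts times voxel volume", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1:10, 1:10] <- 0L
  lab[1:10, 1:5, 1:5] <- 1L # 250 bone voxels
  labels <- label_volume(lab, 2)
  tv <- array(TRUE, dim(lab)) # 1000-voxel TV
  rep <- compartment_volumes(labels, tv)
  expect_equal(rep$bvtv, 0.25)
  expect_equal(rep$mevtv, 0)
  expect_equal(rep$bv_um3, 250 * 8)
})

test_that("phantom report volumes equal ground-truth counts exactly", {
  out <- generate_labels(small_spec(seed = 6))
  rep <- morphometry_report(out$labels)
  cnt <- out$truth$class_counts
  vv3 <- voxel_volume_um3(out$labels)
  expect_identical(rep$n_bone, unname(cnt["bone"]))
  expect_identical(rep$n_vessel, unname(cnt["vessel"]))
  expect_identical(rep$n_met, unname(cnt["metastasis"]))
  expect_equal(rep$bv_um3, cnt[["bone"]] * vv3)
  # structural invariants
  bone <- class_mask(out$labels, "bone")
  tv <- total_volume_mask(out$labels)
  expect_true(all(tv[bone]))
  expect_true(all(c(rep$bvtv, rep$vvtv, rep$mevtv) >= 0))
  expect_true(all(c(rep$bvtv, rep$vvtv, rep$mevtv) <= 1))
  expect_lte(rep$n_bone + rep$n_vessel + rep$n_met, rep$n_tv)
})

test_that("exact distances: axis case, zero on the reference, and
          brute-force equality on random anisotropic instances", {
  ref <- array(FALSE, c(16, 8, 8)); ref[1, 1, 1] <- TRUE
  d <- distance_transform(ref, 3.5)
  expect_equal(d[11, 1, 1], 35) # 10 voxels along x at 3.5 um
  expect_identical(d[1, 1, 1], 0)
  set.seed(4)
  for (i in 1:6) {
    vs <- if (i %% 2 == 0) c(3.5, 3.5, 3.5) else runif(3, 1, 4)
    m <- rand_mask(c(16, 16, 16), 0.05)
    if (!any(m)) next
    dm <- distance_transform(m, vs)
    expect_equal(as.vector(dm), as.vector(bf_edt(m, vs)), tolerance = 1e-9)
  }
})

test_that("VMI averages vessel-to-metastasis distances and flags the
          undefined cases", {
  v <- array(FALSE, c(8, 8, 8)); v[4, 4, 4] <- TRUE
  m <- array(FALSE, c(8, 8, 8)); m[5, 4, 4] <- TRUE
  expect_equal(vmi(v, m, 3.5)$vmi_um, 3.5)
  # vessels inside the metastasis compartment
  expect_equal(vmi(m, m, 3.5)$vmi_um, 0)
  # random masks against the brute-force mean
  set.seed(13)
  vv <- rand_mask(c(10, 10, 10), 0.2)
  mm <- rand_mask(c(10, 10, 10), 0.1)
  res <- vmi(vv, mm, c(2, 3, 1))
  expect_equal(res$vmi_um, mean(bf_edt(mm, c(2, 3, 1))[vv]), tolerance = 1e-12)
  # undefined / error semantics
  none <- array(FALSE, c(8, 8, 8))
  und <- vmi(v, none, 3.5)
  expect_true(und$undefined)
  expect_true(is.na(und$vmi_um))
  expect_error(vmi(none, m, 3.5), "vessel")
})

test_that("local thickness recovers sphere and cylinder diameters and the
          isolated-voxel convention", {
  dims <- c(24, 24, 24)
  # sphere centred on a voxel centre (half-integer physical coordinates)
  sph <- voxelize_sphere(dims, 1, c(12.5, 12.5, 12.5), 8)
  th <- local_thickness(sph, 1)
  centre_th <- th$map[13, 13, 13]
  expect_lt(abs(centre_th - 16), 1)
  expect_lt(abs(th$mean_um - 16), 1)
  one <- array(FALSE, c(8, 8, 8)); one[4, 4, 4] <- TRUE
  expect_equal(local_thickness(one, 3.5)$mean_um, 3.5)
  cyl <- voxelize_capsule(c(16, 16, 40), 1, c(8.5, 8.5, -10), c(8.5, 8.5, 50), 5)
  thc <- local_thickness(cyl, 1)
  expect_lt(abs(median(thc$map[cyl]) - 10), 1)
  expect_error(local_thickness(array(FALSE, c(4, 4, 4)), 1), "empty")
})

test_that("local thickness equals the brute-force inscribed-sphere oracle", {
  set.seed(19)
  blob <- voxelize_sphere(c(14, 14, 14), 1, c(7, 7, 7), 4) |
    voxelize_capsule(c(14, 14, 14), 1, c(3, 3, 3), c(11, 11, 9), 2)
  th <- local_thickness(blob, 1)
  expect_equal(as.vector(th$map), as.vector(bf_thickness(blob, 1)),
               tolerance = 1e-9)
  # anisotropic voxels
  th2 <- local_thickness(blob, c(1, 1.5, 2))
  expect_equal(as.vector(th2$map),
               as.vector(bf_thickness(blob, c(1, 1.5, 2))), tolerance = 1e-9)
})

test_that("the VOI mask is a thresholded distance field intersected with
          TV, monotone in the threshold", {
  out <- generate_labels(small_spec(seed = 28))
  labels <- out$labels
  vs <- voxel_size(labels)
  tv <- total_volume_mask(labels)
  met <- class_mask(labels, "metastasis")
  # sub-voxel threshold: only zero-distance (metastasis) voxels qualify
  tiny <- voi_mask(met, tv, min(vs) / 2, vs)
  expect_identical(which(tiny), which(met & tv))
  # threshold beyond the grid diagonal: the whole TV mask
  diag_um <- sqrt(sum((dim(labels) * vs)^2))
  expect_identical(which(voi_mask(met, tv, diag_um + 1, vs)), which(tv))
  counts <- vapply(c(20, 50, 100, 200, 400),
                   function(t) sum(voi_mask(met, tv, t, vs)), 0L)
  expect_true(all(diff(counts) >= 0))
  expect_error(voi_mask(array(FALSE, dim(labels)), tv, 700, vs), "undefined")
})

test_that("local metrics reduce to global ones on the full TV mask and
          flag vessel-free VOIs", {
  out <- generate_labels(small_spec(seed = 34))
  labels <- out$labels
  tv <- total_volume_mask(labels)
  glob <- compartment_volumes(labels, tv)
  loc <- local_metrics(labels, tv)
  # identical denominators except that global counts span the whole grid:
  # on this phantom every compartment voxel lies inside TV
  expect_equal(loc$vvtv, glob$vvtv)
  expect_equal(loc$bvtv, glob$bvtv)
  voi_empty_vessel <- !class_mask(labels, "vessel") & tv
  # carve a VOI without vessels from a bone-only corner
  corner <- array(FALSE, dim(labels)); corner[1:6, 1:6, 1:6] <- TRUE
  voi0 <- corner & tv & !class_mask(labels, "vessel")
  if (any(voi0)) {
    l0 <- local_metrics(labels, voi0)
    expect_equal(l0$vvtv, 0)
    expect_true(l0$vth_undefined)
    expect_true(is.na(l0$vth_um))
  }
})

test_that("vessel radii shrunk near the lesion depress local V.Th below
          global V.Th", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64), voxel_size_um = 20,
                       shell = list(outer_radius_um = 520, wall_um = 80,
                                    taper = 0.15),
                       trabeculae = list(n_rods = 110, rod_radius_um = 40),
                       vessels = list(n_branches = 8,
                                      radius_range_um = c(40, 80),
                                      radius_factor = 0.6,
                                      effect_distance_um = 250,
                                      min_branch_length_um = 800),
                       metastases = list(n_lesions = 1,
                                         semi_axes_range_um = c(240, 280)),
                       seed = 9)
  out <- generate_labels(spec)
  labels <- out$labels
  vs <- voxel_size(labels)
  tv <- total_volume_mask(labels)
  vessel <- class_mask(labels, "vessel")
  met <- class_mask(labels, "metastasis")
  th <- local_thickness(vessel, vs)
  voi <- voi_mask(met, tv, 250, vs)
  loc <- local_metrics(labels, voi, th$map, 250)
  expect_lt(loc$vth_um, th$mean_um)
})

test_that("reports are invariant under whole-voxel translations", {
  out <- generate_labels(small_spec(seed = 44))
  lab <- unclass(out$labels)
  d <- dim(lab)
  # two copies at different offsets, both with a background margin on
  # every side so no structure touches the grid boundary
  place <- function(off) {
    big <- array(0L, d + c(6, 6, 6))
    big[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
        off[3] + seq_len(d[3])] <- lab
    big
  }
  r1 <- morphometry_report(label_volume(place(c(1, 1, 1)), 3.5),
                           closing_radius_um = 10.5)
  r2 <- morphometry_report(label_volume(place(c(4, 2, 5)), 3.5),
                           closing_radius_um = 10.5)
  for (f in c("n_tv", "n_bone", "n_vessel", "n_met", "bvtv", "vvtv",
              "mevtv", "vth_um", "vmi_um")) {
    expect_equal(r1[[f]], r2[[f]], info = f)
  }
})

test_that("mean vessel thickness recovers known cylinder radii within one
          voxel", {
  for (r in c(3, 5, 8)) {
    dims <- c(2 * r + 10, 2 * r + 10, 44)
    ax <- dims[1] / 2 + 0.5 # axis through voxel centres
    cyl <- voxelize_capsule(dims, 1, c(ax, ax, -10), c(ax, ax, 60), r)
    th <- local_thickness(cyl, 1)
    expect_gte(th$mean_um, 2 * r - 1)
    expect_lte(th$mean_um, 2 * r + 1)
  }
})
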