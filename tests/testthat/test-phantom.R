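# Phantom generator: determinism, label bookkeeping, voxelisation accuracy
# and cohort effect injection.

test_that("generation is deterministic and labels are exclusive", {
  spec <- small_spec(seed = 21)
  a <- generate_labels(spec)
  b <- generate_labels(spec)
  expect_identical(unclass(a$labels), unclass(b$labels))
  counts <- a$truth$class_counts
  expect_identical(sum(counts), length(a$labels))
  expect_identical(unname(counts),
                   tabulate(as.vector(a$labels) + 1L, nbins = 4L))
  # branch ids live exactly on the vessel class
  expect_true(all(a$truth$branch_id[unclass(a$labels) != 2L] == 0L))
  expect_true(all(a$truth$branch_id[unclass(a$labels) == 2L] > 0L))
})

test_that("a spec without lesions yields no metastasis voxels", {
  out <- generate_labels(small_spec(seed = 3,
                                    metastases = list(n_lesions = 0)))
  expect_identical(unname(out$truth$class_counts["metastasis"]), 0L)
  expect_false(any(unclass(out$labels) == 3L))
})

test_that("sphere voxelisation matches brute force exactly and the analytic
          volume within 2%", {
  dims <- c(28, 28, 28)
  vs <- c(1, 1, 1)
  centre <- c(14.2, 13.7, 14.5)
  m <- voxelize_sphere(dims, vs, centre, 10)
  expect_identical(sum(m), bf_sphere_count(dims, vs, centre, 10))
  expect_lt(abs(sum(m) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("voxelised counts track analytic volumes within 2% for radii of
          5 voxels and above", {
  set.seed(17)
  for (i in 1:10) {
    r <- runif(1, 5, 9)
    dims <- rep(ceiling(2 * r) + 6, 3)
    centre <- dims / 2 + runif(3, -0.4, 0.4)
    m <- voxelize_sphere(dims, 1, centre, r)
    va <- 4 / 3 * pi * r^3
    expect_lt(abs(sum(m) - va) / va, 0.02)
    # tilted capsule (as the vessel sweeps are): cylinder plus two caps
    L <- 26
    dir <- c(runif(2, 0.15, 0.35), 1)
    dir <- dir / sqrt(sum(dir^2))
    n <- ceiling(2 * r + L * max(dir[1:2]) + 8)
    a <- c(r + 4, r + 4, r + 4)
    b <- a + L * dir
    dims_c <- c(n, n, ceiling(b[3] + r + 4))
    cap <- voxelize_capsule(dims_c, 1, a, b, r)
    vc <- pi * r^2 * L + 4 / 3 * pi * r^3
    expect_lt(abs(sum(cap) - vc) / vc, 0.02)
  }
})

test_that("degenerate grids and invalid specs are rejected", {
  expect_error(phantom_spec(grid_shape = c(4, 64, 64)), "degenerate")
  expect_error(phantom_spec(vessels = list(radius_range_um = c(10, 6))),
               "radius_range")
  expect_error(phantom_spec(render = list(
    means = c(background = 0.5, marrow = 0.3, bone = 0.7, vessel = 0.9))),
    "background < marrow")
  expect_error(phantom_spec(metastases = list(semi_axes_range_um = c(100, 120))),
               "semi-axes")
  expect_error(
    generate_labels(small_spec(metastases = list(
      n_lesions = 1, semi_axes_range_um = c(54, 55), max_retries = 3))),
    "could not place lesion")
})

test_that("cohorts regenerate identically and group effects act as
          constructed", {
  co <- cohort_spec(groups = list(
    list(label = "A", n = 3),
    list(label = "C", n = 3, radius_factor = 0.6, effect_distance_um = 700)),
    base = small_spec(), seed = 12)
  s1 <- generate_cohort(co)
  s2 <- generate_cohort(co)
  expect_identical(lapply(s1, function(s) unclass(s$labels)),
                   lapply(s2, function(s) unclass(s$labels)))
  # shrunk group: applied segment radii are exactly 0.6 x base in the
  # effect region, untouched outside it
  for (s in s1[4:6]) {
    seg <- s$truth$segments
    expect_true(all(seg$radius_um[seg$in_effect] ==
                      0.6 * seg$base_radius_um[seg$in_effect]))
    expect_true(all(seg$radius_um[!seg$in_effect] ==
                      seg$base_radius_um[!seg$in_effect]))
    expect_gt(sum(seg$in_effect), 0)
  }
  # null group: no segment altered
  for (s in s1[1:3]) {
    expect_true(all(s1[[1]]$truth$segments$radius_um ==
                      s1[[1]]$truth$segments$base_radius_um))
  }
})

test_that("a null cohort shows no systematic group difference in true
          vessel radii", {
  co <- cohort_spec(groups = list(list(label = "A", n = 4),
                                  list(label = "B", n = 4)),
                    base = small_spec(), seed = 31)
  samples <- generate_cohort(co)
  mean_r <- vapply(samples, function(s) mean(s$truth$branch_radii_um), 0)
  grp <- vapply(samples, function(s) s$group, "")
  # both groups draw from U(6, 10); means should straddle 8 within noise
  expect_lt(abs(mean(mean_r[grp == "A"]) - mean(mean_r[grp == "B"])), 1.5)
})

test_that("effects producing sub-voxel radii are rejected", {
  co <- cohort_spec(groups = list(
    list(label = "C", n = 2, radius_factor = 0.2)),
    base = small_spec(), seed = 1)
  expect_error(generate_cohort(co), "sub-voxel")
})
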