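# Dice evaluation and the classical baseline segmenter.

test_that("dice_coefficient handles the canonical cases", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
  expect_identical(dice_coefficient(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[3:4, 4, 4] <- TRUE
  expect_identical(dice_coefficient(a, b), 0)
  # |A| = 4, |B| = 4, |A intersect B| = 2
  a2 <- array(FALSE, c(4, 4, 4)); a2[1:4, 1, 1] <- TRUE
  b2 <- array(FALSE, c(4, 4, 4)); b2[3:4, 1, 1] <- TRUE; b2[1:2, 2, 1] <- TRUE
  expect_equal(dice_coefficient(a2, b2), 0.5)
  empty <- array(FALSE, c(4, 4, 4))
  expect_identical(dice_coefficient(empty, empty), 1)
  expect_error(dice_coefficient(a, array(FALSE, c(4, 4, 5))), "shape")
})

test_that("dice is symmetric, matches set arithmetic exactly, and grows
          with the intersection", {
  set.seed(8)
  for (i in 1:100) {
    a <- rand_mask(c(16, 16, 16), runif(1, 0.02, 0.4))
    b <- rand_mask(c(16, 16, 16), runif(1, 0.02, 0.4))
    d <- dice_coefficient(a, b)
    expect_identical(d, dice_coefficient(b, a))
    expect_identical(d, bf_dice(a, b))
  }
  # monotonicity: growing the overlap with |A|, |B| fixed never lowers Dice
  set.seed(9)
  a <- rand_mask(c(12, 12, 12), 0.3)
  b <- array(FALSE, dim(a))
  outside <- which(!a)
  inside <- which(a)
  b[outside[1:50]] <- TRUE
  prev <- dice_coefficient(a, b)
  for (k in seq(5, 50, by = 5)) {
    b2 <- b
    b2[outside[1:k]] <- FALSE        # swap k outside voxels...
    b2[inside[1:k]] <- TRUE          # ...for k overlap voxels
    d <- dice_coefficient(a, b2)
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("dice_report scores classes separately and matches the
          closed-form single-voxel perturbation", {
  out <- generate_labels(small_spec(seed = 14))
  ref <- out$labels
  expect_equal(dice_report(ref, ref)$dice, rep(1, 3))
  bg <- label_volume(array(0L, dim(ref)), voxel_size(ref))
  expect_equal(dice_report(bg, ref)$dice, rep(0, 3))
  # flip one vessel voxel to background: Dice = 2(n-1) / (2n-1)
  seg <- unclass(ref)
  vi <- which(seg == 2L)
  n <- length(vi)
  seg[vi[1]] <- 0L
  rep2 <- dice_report(label_volume(seg, voxel_size(ref)), ref)
  expect_equal(rep2$dice[rep2$class == "vessel"], 2 * (n - 1) / (2 * n - 1))
})

test_that("unknown class ids are rejected", {
  expect_error(label_volume(array(c(0L, 7L), c(2, 2, 2)), 3.5), "7")
})

test_that("the baseline segmenter recovers a noise-free phantom and
          reports no metastases when there are none", {
  spec <- small_spec(seed = 23,
                     render = list(blur_sigma_um = 0, noise_sd = 0))
  out <- generate_labels(spec)
  img <- render_intensity(out$labels, spec)
  # cavity-inference scale sits between the trabecular pore size and the
  # (small) lesions of this fixture
  pars <- segmenter_params(smooth_sigma_um = 0, closing_radius_um = 24.5)
  seg <- baseline_segment(img, pars)
  dr <- dice_report(seg, out$labels)
  expect_true(all(dr$dice >= 0.95))
  # lesion-free phantom: no false cavities
  spec0 <- small_spec(seed = 23, metastases = list(n_lesions = 0),
                      render = list(blur_sigma_um = 0, noise_sd = 0))
  out0 <- generate_labels(spec0)
  seg0 <- baseline_segment(render_intensity(out0$labels, spec0), pars)
  expect_false(any(unclass(seg0) == 3L))
})

test_that("pure background raises a no-bone error", {
  img <- intensity_volume(array(0.05, c(16, 16, 16)), 3.5)
  expect_error(baseline_segment(img), "no bone detected")
})

test_that("the calibration-size sweep returns one row per size and class
          and validates its inputs", {
  co <- cohort_spec(groups = list(list(label = "A", n = 5)),
                    base = small_spec(), seed = 41)
  samples <- generate_cohort(co)
  expect_identical(nrow(training_size_experiment(samples, integer(0))), 0L)
  expect_error(training_size_experiment(samples, sizes = 10), "exceed")
  pars <- segmenter_params(closing_radius_um = 24.5)
  res <- training_size_experiment(samples, sizes = c(1, 3), n_test = 2,
                                  params = pars)
  expect_identical(nrow(res), 6L)
  expect_setequal(unique(res$size), c(1L, 3L))
  expect_true(all(res$dice_mean >= 0 & res$dice_mean <= 1))
  # degenerate split: test set = calibration set reduces to self-evaluation
  res_self <- training_size_experiment(samples, sizes = 5, n_test = 0,
                                       params = pars)
  expect_true(all(res_self$dice_mean > 0.5))
})
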