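# Dice evaluation of multi-class segmentations and a classical
# intensity-based baseline segmenter. The segmenter thresholds bone and
# contrast-filled vessels, then infers metastases as large cavities that
# remain open after morphologically closing the bone mask: osteolytic
# lesions carry no intrinsic contrast and are detectable only as missing
# bone structure.

#' Dice coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Symmetric; defined as 1 when both
#' masks are empty (perfect agreement on absence).
#'
#' @param seg_mask,ref_mask logical 3D arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(seg_mask, ref_mask) {
  seg_mask <- .check_mask(seg_mask, "seg_mask")
  ref_mask <- .check_mask(ref_mask, "ref_mask")
  .same_shape(seg_mask, ref_mask, "masks")
  na <- sum(seg_mask)
  nb <- sum(ref_mask)
  if (na + nb == 0) return(1)
  2 * sum(seg_mask & ref_mask) / (na + nb)
}

#' Per-class Dice report for a multi-class segmentation
#'
#' One Dice coefficient per foreground class (bone, vessel, metastasis);
#' the background is excluded. The stored voxel counts allow the Dice
#' values to be recomputed exactly.
#'
#' @param seg,ref [label_volume()] objects on the same grid and class
#'   vocabulary.
#' @return data.frame with one row per class: `class`, `n_seg`, `n_ref`,
#'   `n_intersect`, `dice`.
#' @export
dice_report <- function(seg, ref) {
  stopifnot(inherits(seg, "label_volume"), inherits(ref, "label_volume"))
  .same_shape(seg, ref, "segmentation and reference")
  classes <- c(bone = 1L, vessel = 2L, metastasis = 3L)
  rows <- lapply(names(classes), function(cl) {
    a <- class_mask(seg, cl)
    b <- class_mask(ref, cl)
    data.frame(class = cl, n_seg = sum(a), n_ref = sum(b),
               n_intersect = sum(a & b),
               dice = dice_coefficient(a, b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Baseline segmenter parameters
#'
#' @param smooth_sigma_um Gaussian smoothing width before thresholding.
#' @param thresholds optional numeric `c(t_bone, t_vessel)`: voxels in
#'   `(t_bone, t_vessel]` become bone, above `t_vessel` vessel. When `NULL`
#'   the thresholds are found by hierarchical two-class Otsu (foreground vs
#'   background, then bone vs vessel), which is parameter-free.
#' @param min_component_voxels named minimum component sizes for the bone
#'   and vessel classes; smaller 26-connected components are discarded.
#' @param closing_radius_um radius of the ball used to close the bone mask
#'   when estimating the bone envelope for metastasis inference.
#' @param min_cavity_voxels cavities below this size are treated as normal
#'   inter-trabecular space, not metastases.
#' @return a `segmenter_params` list.
#' @export
segmenter_params <- function(smooth_sigma_um = 1,
                             thresholds = NULL,
                             min_component_voxels = c(bone = 50, vessel = 10),
                             closing_radius_um = NULL,
                             min_cavity_voxels = 50) {
  if (!is.null(thresholds)) {
    if (length(thresholds) != 2L || thresholds[1] >= thresholds[2]) {
      stop("thresholds must be increasing: c(t_bone, t_vessel)")
    }
  }
  structure(list(smooth_sigma_um = smooth_sigma_um,
                 thresholds = thresholds,
                 min_component_voxels = min_component_voxels,
                 closing_radius_um = closing_radius_um,
                 min_cavity_voxels = min_cavity_voxels),
            class = "segmenter_params")
}

# Hierarchical auto-thresholds: two-class Otsu separates foreground from
# background, then a second Otsu splits bone from vessel on the foreground
# eroded by one voxel, which excludes the partial-volume boundary shell
# whose intensity ramp would otherwise attract the split.
.auto_thresholds <- function(v, vs) {
  t1 <- .otsu(as.vector(v))
  fg <- v > t1
  if (!any(fg)) stop("no bone detected: empty foreground after thresholding")
  core <- erode_ball(fg, min(vs), vs)
  t2 <- .otsu(v[if (any(core)) core else fg])
  c(t1, t2)
}

# Otsu threshold from a numeric sample (maximises between-class variance
# over a 256-bin histogram).
.otsu <- function(v, nbins = 256L) {
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Segment an intensity volume into bone, vessel and metastasis
#'
#' Classical baseline pipeline: Gaussian smoothing, (auto-)thresholding
#' into bone and vessel, removal of small components, then metastasis
#' inference: the bone mask is closed with a Euclidean ball (absorbing
#' normal inter-trabecular space), its holes are filled to obtain the bone
#' envelope, and envelope-interior cavities that survive the closing, are
#' not occupied by bone or vessel, and exceed a minimum size are labelled
#' metastasis. Deterministic.
#'
#' @param img an [intensity_volume()].
#' @param params a [segmenter_params()].
#' @return a [label_volume()].
#' @export
baseline_segment <- function(img, params = segmenter_params()) {
  stopifnot(inherits(img, "intensity_volume"),
            inherits(params, "segmenter_params"))
  vs <- voxel_size(img)
  v <- unclass(img)
  if (params$smooth_sigma_um > 0) {
    v <- .cpp_gaussian_blur(as.vector(v), .as_dim(img),
                            params$smooth_sigma_um / vs)
    dim(v) <- dim(img)
  }
  thr <- if (is.null(params$thresholds)) .auto_thresholds(v, vs)
         else params$thresholds
  bone <- v > thr[1] & v <= thr[2]
  vessel <- v > thr[2]
  if (!any(bone)) stop("no bone detected after thresholding")
  mcv <- params$min_component_voxels
  bone <- filter_small_components(bone, mcv[["bone"]])
  vessel <- filter_small_components(vessel, mcv[["vessel"]])
  if (!any(bone)) stop("no bone detected after component filtering")
  cr <- params$closing_radius_um
  if (is.null(cr)) cr <- 10 * min(vs)
  # bounded closing keeps structures cut by the stack faces closed, so the
  # marrow canal is not mistaken for a cavity at the cut planes
  closed <- close_ball(bone, cr, vs, bounded = TRUE)
  envelope <- fill_holes(closed, sealed_faces = "z")
  cavities <- envelope & !closed & !vessel
  met <- filter_small_components(cavities, params$min_cavity_voxels,
                                 connectivity = 6)
  lab <- array(0L, dim(img))
  lab[bone] <- 1L
  lab[vessel] <- 2L
  lab[met] <- 3L
  label_volume(lab, vs)
}

#' Calibration-set-size sweep for the baseline segmenter
#'
#' Emulates a training-set-size experiment for the auto-thresholded
#' baseline: for each size, thresholds are calibrated on that many
#' calibration samples (hierarchical Otsu on their pooled intensities) and
#' per-class Dice is evaluated against ground truth on a fixed test set.
#' Median Dice is reported, not asserted monotone.
#'
#' @param cohort list of samples as from [generate_cohort()], each with
#'   `labels` and `spec` (intensities are rendered on the fly).
#' @param sizes integer calibration-set sizes; each must be at most the
#'   number of calibration samples available.
#' @param n_test number of samples (from the end of the cohort) held out
#'   as the fixed test set.
#' @param params base [segmenter_params()]; its thresholds are overridden
#'   by the calibrated ones.
#' @return data.frame with one row per (size, class): mean and SD of Dice
#'   over the test set. Empty `sizes` yields an empty table.
#' @export
training_size_experiment <- function(cohort, sizes, n_test = 2,
                                     params = segmenter_params()) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0) {
    return(data.frame(size = integer(0), class = character(0),
                      dice_mean = numeric(0), dice_sd = numeric(0)))
  }
  n_cal <- length(cohort) - n_test
  if (any(sizes > n_cal)) {
    stop("calibration sizes exceed the ", n_cal, " available samples")
  }
  test_idx <- seq(length(cohort) - n_test + 1L, length(cohort))
  if (n_test == 0) test_idx <- seq_along(cohort) # degenerate self-evaluation
  imgs <- lapply(cohort, function(s) render_intensity(s$labels, s$spec))
  # per-sample auto-thresholds on the smoothed image, as the segmenter
  # itself would compute them
  thr_all <- t(vapply(imgs, function(im) {
    v <- unclass(im)
    vs <- voxel_size(im)
    if (params$smooth_sigma_um > 0) {
      v <- .cpp_gaussian_blur(as.vector(v), .as_dim(im),
                              params$smooth_sigma_um / vs)
      dim(v) <- dim(im)
    }
    .auto_thresholds(v, vs)
  }, numeric(2)))
  out <- list()
  for (sz in sizes) {
    p <- params
    p$thresholds <- colMeans(thr_all[seq_len(sz), , drop = FALSE])
    dice <- lapply(test_idx, function(i) {
      seg <- baseline_segment(imgs[[i]], p)
      dice_report(seg, cohort[[i]]$labels)
    })
    dice <- do.call(rbind, dice)
    agg_m <- tapply(dice$dice, dice$class, mean)
    agg_s <- tapply(dice$dice, dice$class, sd)
    out[[length(out) + 1L]] <- data.frame(
      size = sz, class = names(agg_m),
      dice_mean = as.numeric(agg_m), dice_sd = as.numeric(agg_s),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
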