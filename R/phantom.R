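# Synthetic tibia-like phantoms with known ground truth. A phantom is a
# cortical shell with a trabecular rod network, contrast-filled vessel
# branches generated as piecewise-linear random walks swept with a circular
# cross-section, and osteolytic metastasis lesions modelled as ellipsoids
# centred on bone voxels so they appear purely as missing bone. Where
# primitives overlap the label precedence is metastasis > vessel > bone.

#' Phantom specification
#'
#' Defines the geometry, rendering model and seed for one synthetic
#' labelled volume. All physical quantities are in micrometres. The default
#' grid is 64^3 voxels of 3.5 um, i.e. a 224 um cube containing a tapered
#' cortical shell, a dense trabecular rod network, a handful of tortuous
#' vessel branches and two osteolytic lesions.
#'
#' @param grid_shape voxel counts per axis `(x, y, z)`.
#' @param voxel_size_um voxel edge lengths, scalar or length 3.
#' @param shell list: `outer_radius_um` (outer cortical radius at the base),
#'   `wall_um` (cortical wall thickness), `taper` (fractional radius
#'   reduction from bottom to top slice).
#' @param trabeculae list: `n_rods` (number of random rods spanning the
#'   marrow), `rod_radius_um`.
#' @param vessels list: `n_branches`, `radius_range_um` (per-branch radius
#'   drawn uniformly), `tortuosity` (direction perturbation per step),
#'   `min_branch_length_um`, and optionally `radius_factor` /
#'   `effect_distance_um` applied to segments within that distance of the
#'   metastasis compartment (used to inject treatment effects in cohorts).
#' @param metastases list: `n_lesions`, `semi_axes_range_um` (ellipsoid
#'   semi-axes drawn uniformly), `max_retries` for lesion placement.
#' @param render list: `means` (named intensities for background, marrow,
#'   bone, vessel; metastases always render at the marrow mean since they
#'   carry no intrinsic contrast), `blur_sigma_um` (partial-volume
#'   emulation), `noise_sd` (additive Gaussian noise).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_um = 3.5,
                         shell = list(),
                         trabeculae = list(),
                         vessels = list(),
                         metastases = list(),
                         render = list(),
                         seed = 1L) {
  vs <- .check_voxel_size(voxel_size_um)
  shell <- utils::modifyList(
    list(outer_radius_um = 91, wall_um = 14, taper = 0.15), shell)
  trabeculae <- utils::modifyList(
    list(n_rods = 110, rod_radius_um = 7), trabeculae)
  vessels <- utils::modifyList(
    list(n_branches = 8, radius_range_um = c(7, 14), tortuosity = 0.35,
         min_branch_length_um = 150, radius_factor = 1,
         effect_distance_um = 700), vessels)
  metastases <- utils::modifyList(
    list(n_lesions = 2, semi_axes_range_um = c(42, 56), max_retries = 25),
    metastases)
  render <- utils::modifyList(
    list(means = c(background = 0.05, marrow = 0.25, bone = 0.65,
                   vessel = 0.90),
         blur_sigma_um = 2, noise_sd = 0.02), render)
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         voxel_size_um = vs, shell = shell,
                         trabeculae = trabeculae, vessels = vessels,
                         metastases = metastases, render = render,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  .validate_phantom_spec(spec)
  spec
}

.validate_phantom_spec <- function(spec) {
  gs <- spec$grid_shape
  if (length(gs) != 3L || any(!is.finite(gs))) {
    stop("grid_shape must be three voxel counts")
  }
  if (any(gs < 8L)) stop("degenerate grid: need at least 8 voxels per axis")
  sh <- spec$shell
  if (sh$outer_radius_um <= 0 || sh$wall_um <= 0 ||
      sh$wall_um >= sh$outer_radius_um) {
    stop("shell radii must be positive with wall thinner than outer radius")
  }
  if (sh$taper < 0 || sh$taper >= 1) stop("shell taper must be in [0, 1)")
  tr <- spec$trabeculae
  if (tr$n_rods < 0 || tr$rod_radius_um <= 0) {
    stop("trabecular rod count must be >= 0 with positive radius")
  }
  ve <- spec$vessels
  rr <- ve$radius_range_um
  if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2]) {
    stop("vessel radius_range_um must be a positive increasing pair")
  }
  if (rr[2] >= sh$outer_radius_um) {
    stop("vessel radii must be smaller than the shell outer radius")
  }
  if (ve$radius_factor <= 0 || ve$radius_factor > 2) {
    stop("vessel radius_factor must be in (0, 2]")
  }
  if (ve$radius_factor * rr[1] < min(spec$voxel_size_um)) {
    stop("vessel radius_factor ", ve$radius_factor,
         " would produce sub-voxel vessel radii (",
         format(ve$radius_factor * rr[1]), " um < one voxel edge)")
  }
  me <- spec$metastases
  sa <- me$semi_axes_range_um
  if (me$n_lesions < 0) stop("lesion count must be >= 0")
  if (length(sa) != 2L || any(sa <= 0) || sa[1] > sa[2]) {
    stop("lesion semi_axes_range_um must be a positive increasing pair")
  }
  if (me$n_lesions > 0 && sa[2] >= sh$outer_radius_um) {
    stop("lesion semi-axes must be smaller than the shell outer radius")
  }
  m <- spec$render$means
  need <- c("background", "marrow", "bone", "vessel")
  if (!all(need %in% names(m))) {
    stop("render means must name background, marrow, bone and vessel")
  }
  if (!(m["background"] < m["marrow"] && m["marrow"] < m["bone"])) {
    stop("render means must satisfy background < marrow < bone")
  }
  if (m["vessel"] <= m["marrow"] || m["vessel"] == m["bone"]) {
    stop("vessel mean must exceed the marrow mean and differ from bone")
  }
  if (spec$render$blur_sigma_um < 0 || spec$render$noise_sd < 0) {
    stop("blur width and noise scale must be non-negative")
  }
  invisible(spec)
}

#' Rasterise geometric primitives onto a voxel grid
#'
#' A voxel belongs to the primitive when its centre does (centre-in test);
#' the centre of voxel `(i, j, k)` (1-based) is at `(i - 0.5) *`
#' voxel size, per axis. These are the rasterisers the phantom generator
#' sweeps its shapes with, exposed so voxelised counts can be compared
#' against analytic volumes.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_size_um voxel edge lengths, scalar or length 3.
#' @param centre_um,semi_axes_um ellipsoid centre and semi-axes (physical
#'   units); a sphere is the equal-semi-axis case.
#' @param a_um,b_um capsule segment endpoints; `radius_um` its radius.
#' @return logical array of shape `grid_shape`.
#' @export
voxelize_ellipsoid <- function(grid_shape, voxel_size_um, centre_um,
                               semi_axes_um) {
  gs <- as.integer(grid_shape)
  vs <- .check_voxel_size(voxel_size_um)
  if (any(semi_axes_um <= 0)) stop("semi-axes must be positive")
  vol <- integer(prod(gs))
  .cpp_paint_ellipsoid(vol, gs, vs, as.numeric(centre_um),
                       as.numeric(rep(semi_axes_um, length.out = 3)), 1L)
  dim(vol) <- gs
  vol == 1L
}

#' @rdname voxelize_ellipsoid
#' @param radius_um sphere or capsule radius.
#' @export
voxelize_sphere <- function(grid_shape, voxel_size_um, centre_um,
                            radius_um) {
  voxelize_ellipsoid(grid_shape, voxel_size_um, centre_um,
                     rep(radius_um, 3))
}

#' @rdname voxelize_ellipsoid
#' @export
voxelize_capsule <- function(grid_shape, voxel_size_um, a_um, b_um,
                             radius_um) {
  gs <- as.integer(grid_shape)
  vs <- .check_voxel_size(voxel_size_um)
  if (radius_um <= 0) stop("radius must be positive")
  vol <- integer(prod(gs))
  .cpp_paint_capsule(vol, gs, vs, as.numeric(a_um), as.numeric(b_um),
                     radius_um, 1L)
  dim(vol) <- gs
  vol == 1L
}

# voxel-centre coordinates along one axis (physical units, C++ convention:
# centre of 0-based voxel i at (i + 0.5) * spacing)
.axis_centres <- function(n, s) (seq_len(n) - 0.5) * s

# outer cortical radius as a function of z (linear taper)
.shell_radius <- function(spec, z_um) {
  zmax <- spec$grid_shape[3] * spec$voxel_size_um[3]
  spec$shell$outer_radius_um * (1 - spec$shell$taper * z_um / zmax)
}

#' Generate a labelled phantom volume with ground truth
#'
#' Deterministic for a fixed spec (including seed). Label precedence where
#' primitives overlap is metastasis > vessel > bone: lesions erode bone and
#' hide any vessel crossing them (the lesion carries no contrast), vessels
#' tunnel through bone.
#'
#' @param spec a [phantom_spec()].
#' @return list with `labels` (a [label_volume()]) and `truth`, a
#'   `phantom_truth` list holding per-class voxel counts, lesion centres,
#'   semi-axes and analytic volumes, per-branch vessel radii, a per-voxel
#'   vessel branch-id array, and the per-segment radius table (with the
#'   effect-region flag used by cohort effects).
#' @export
generate_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .validate_phantom_spec(spec)
  .with_seed(spec$seed, {
    gs <- spec$grid_shape
    vs <- spec$voxel_size_um
    n <- prod(gs)
    xc <- .axis_centres(gs[1], vs[1])
    yc <- .axis_centres(gs[2], vs[2])
    zc <- .axis_centres(gs[3], vs[3])
    cx <- gs[1] * vs[1] / 2
    cy <- gs[2] * vs[2] / 2
    rxy <- sqrt(outer((xc - cx)^2, (yc - cy)^2, `+`)) # nx x ny
    r_out <- .shell_radius(spec, zc)                  # per slice
    r_in <- pmax(r_out - spec$shell$wall_um, 0)

    # cortical shell
    rxy_arr <- array(rxy, dim = gs)
    r_out_arr <- array(rep(r_out, each = gs[1] * gs[2]), dim = gs)
    r_in_arr <- array(rep(r_in, each = gs[1] * gs[2]), dim = gs)
    interior <- rxy_arr < r_out_arr
    bone <- interior & (rxy_arr >= r_in_arr)

    # trabecular rods: random chords through the marrow
    bone_vol <- as.integer(bone)
    tr <- spec$trabeculae
    if (tr$n_rods > 0) {
      for (r in seq_len(tr$n_rods)) {
        ends <- .sample_marrow_points(spec, 2L)
        .cpp_paint_capsule(bone_vol, gs, vs, ends[1, ], ends[2, ],
                           tr$rod_radius_um, 1L)
      }
    }
    dim(bone_vol) <- gs
    bone_vol[!interior] <- 0L # clip rods to the outer contour
    bone <- bone_vol == 1L

    # metastasis lesions: ellipsoids centred on bone voxels, fully inside
    # the outer contour
    me <- spec$metastases
    lesion_vol <- integer(n)
    centres <- matrix(numeric(0), 0, 3)
    semis <- matrix(numeric(0), 0, 3)
    if (me$n_lesions > 0) {
      bone_idx <- which(bone)
      for (l in seq_len(me$n_lesions)) {
        placed <- FALSE
        for (try in seq_len(me$max_retries)) {
          semi <- runif(3, me$semi_axes_range_um[1], me$semi_axes_range_um[2])
          cand <- .eligible_lesion_centres(spec, bone_idx, rxy_arr, zc, semi)
          if (length(cand) == 0) next
          ci <- cand[sample.int(length(cand), 1L)]
          centre <- .voxel_centre(ci, gs, vs)
          .cpp_paint_ellipsoid(lesion_vol, gs, vs, centre, semi, 1L)
          centres <- rbind(centres, centre)
          semis <- rbind(semis, semi)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place lesion ", l, " on bone within ",
               me$max_retries, " retries")
        }
      }
    }
    dim(lesion_vol) <- gs
    lesion <- lesion_vol == 1L

    # vessel branches: random walks swept with a circular cross-section;
    # radii shrunk by radius_factor within effect_distance_um of lesions
    ve <- spec$vessels
    vessel_vol <- integer(n)
    branch_vol <- integer(n)
    branch_radii <- numeric(0)
    segments <- list()
    eff_active <- ve$radius_factor != 1 && any(lesion)
    lesion_d2 <- if (eff_active) .edt_sq(lesion, vs) else NULL
    eff_d2 <- ve$effect_distance_um^2
    if (ve$n_branches > 0) {
      step_um <- 4 * min(vs)
      zmax <- gs[3] * vs[3]
      # keep vessels clear of the cut faces so every vessel voxel stays
      # inside the total-volume contour of the (open-ended) cortical tube
      zlo <- 0.08 * zmax + ve$radius_range_um[2]
      zhi <- zmax - zlo
      n_steps <- max(ceiling(ve$min_branch_length_um / step_um),
                     ceiling(0.9 * zmax / step_um))
      for (b in seq_len(ve$n_branches)) {
        base_r <- runif(1, ve$radius_range_um[1], ve$radius_range_um[2])
        branch_radii <- c(branch_radii, base_r)
        p <- .sample_marrow_points(spec, 1L)[1, ]
        p[3] <- min(max(p[3], zlo), zhi)
        dir <- c(rnorm(2, 0, 0.5), sample(c(-1, 1), 1))
        dir <- dir / sqrt(sum(dir^2))
        for (s in seq_len(n_steps)) {
          dir <- dir + ve$tortuosity * rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          q <- p + step_um * dir
          # reflect off the endosteal wall and the axial margins; sweeps
          # may reach into the cortical wall but never breach it
          rq <- sqrt((q[1] - cx)^2 + (q[2] - cy)^2)
          rmax <- 0.9 * max(.shell_radius(spec, min(max(q[3], 0), zmax)) -
                              spec$shell$wall_um, 1e-6)
          if (rq > rmax) {
            nrm <- c(q[1] - cx, q[2] - cy) / rq
            dir[1:2] <- dir[1:2] - 2 * sum(dir[1:2] * nrm) * nrm
            q <- p + step_um * dir
          }
          if (q[3] < zlo || q[3] > zhi) {
            dir[3] <- -dir[3]
            q <- p + step_um * dir
            q[3] <- min(max(q[3], zlo), zhi)
          }
          in_eff <- FALSE
          if (eff_active) {
            mid_idx <- .point_voxel(p, gs, vs)
            in_eff <- lesion_d2[mid_idx] < eff_d2
          }
          seg_r <- if (in_eff) base_r * ve$radius_factor else base_r
          .cpp_paint_capsule(vessel_vol, gs, vs, p, q, seg_r, 1L,
                             branch_vol, b)
          segments[[length(segments) + 1L]] <-
            c(branch = b, radius_um = seg_r, base_radius_um = base_r,
              in_effect = as.numeric(in_eff))
          p <- q
        }
      }
    }
    dim(vessel_vol) <- gs
    dim(branch_vol) <- gs
    vessel_vol[!interior] <- 0L # clip sweeps to the outer contour
    vessel <- vessel_vol == 1L

    # compose with precedence metastasis > vessel > bone
    lab <- integer(n)
    dim(lab) <- gs
    lab[bone] <- 1L
    lab[vessel] <- 2L
    lab[lesion] <- 3L
    branch_vol[lab != 2L] <- 0L
    labels <- label_volume(lab, vs)

    counts <- tabulate(as.vector(lab) + 1L, nbins = 4L)
    names(counts) <- c("background", "bone", "vessel", "metastasis")
    seg_tab <- if (length(segments)) {
      as.data.frame(do.call(rbind, segments))
    } else {
      data.frame(branch = numeric(0), radius_um = numeric(0),
                 base_radius_um = numeric(0), in_effect = numeric(0))
    }
    seg_tab$in_effect <- seg_tab$in_effect > 0
    truth <- structure(list(
      class_counts = counts,
      voxel_size_um = vs,
      lesion_centres_um = centres,
      lesion_semi_axes_um = semis,
      lesion_volumes_um3 = if (nrow(semis)) {
        4 / 3 * pi * semis[, 1] * semis[, 2] * semis[, 3]
      } else numeric(0),
      branch_radii_um = branch_radii,
      branch_id = branch_vol,
      segments = seg_tab
    ), class = "phantom_truth")
    list(labels = labels, truth = truth)
  })
}

# uniform points inside the marrow (radially sqrt-uniform within 0.9 of the
# inner cortical radius)
.sample_marrow_points <- function(spec, n) {
  gs <- spec$grid_shape
  vs <- spec$voxel_size_um
  zmax <- gs[3] * vs[3]
  z <- runif(n, 0.02 * zmax, 0.98 * zmax)
  r_in <- pmax(.shell_radius(spec, z) - spec$shell$wall_um, 1e-6)
  rad <- 0.9 * r_in * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  cbind(gs[1] * vs[1] / 2 + rad * cos(ang),
        gs[2] * vs[2] / 2 + rad * sin(ang),
        z)
}

# bone voxels on which an ellipsoid with the given semi-axes stays inside
# the outer contour and the grid
.eligible_lesion_centres <- function(spec, bone_idx, rxy_arr, zc, semi) {
  gs <- spec$grid_shape
  vs <- spec$voxel_size_um
  zmax <- gs[3] * vs[3]
  semi_xy <- max(semi[1], semi[2])
  k <- arrayInd(bone_idx, gs)
  z_um <- zc[k[, 3]]
  r_out <- .shell_radius(spec, z_um)
  ok <- (rxy_arr[bone_idx] + semi_xy < r_out) &
    (z_um - semi[3] > 0) & (z_um + semi[3] < zmax)
  bone_idx[ok]
}

.voxel_centre <- function(idx, gs, vs) {
  k <- arrayInd(idx, gs)
  as.numeric((k - 0.5) * vs)
}

.point_voxel <- function(p, gs, vs) {
  k <- pmin(pmax(floor(p / vs), 0), gs - 1)
  as.integer(1 + k[1] + gs[1] * (k[2] + gs[2] * k[3]))
}

#' Render a grayscale volume from a labelled phantom
#'
#' Applies the configured compartment mean intensities, then Gaussian blur
#' (partial-volume emulation), then additive Gaussian noise, in that order.
#' Metastasis voxels receive the marrow mean: in contrast-enhanced micro-CT
#' of this kind, metastases carry no intrinsic contrast and are visible
#' only as missing bone structure. Deterministic for a fixed spec.
#'
#' @param labels a [label_volume()] from [generate_labels()] (or compatible
#'   with the spec's grid).
#' @param spec the [phantom_spec()] providing the render model and the
#'   analytic shell geometry (used to distinguish marrow from exterior
#'   background).
#' @return an [intensity_volume()].
#' @export
render_intensity <- function(labels, spec) {
  stopifnot(inherits(labels, "label_volume"), inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  if (!identical(dim(labels), as.integer(gs))) {
    stop("label volume shape does not match the spec grid")
  }
  vs <- spec$voxel_size_um
  m <- spec$render$means
  xc <- .axis_centres(gs[1], vs[1]); yc <- .axis_centres(gs[2], vs[2])
  zc <- .axis_centres(gs[3], vs[3])
  rxy <- sqrt(outer((xc - gs[1] * vs[1] / 2)^2,
                    (yc - gs[2] * vs[2] / 2)^2, `+`))
  interior <- array(rxy, dim = gs) <
    array(rep(.shell_radius(spec, zc), each = gs[1] * gs[2]), dim = gs)
  img <- array(m[["background"]], dim = gs)
  img[interior] <- m[["marrow"]]
  img[unclass(labels) == 1L] <- m[["bone"]]
  img[unclass(labels) == 2L] <- m[["vessel"]]
  img[unclass(labels) == 3L] <- m[["marrow"]] # no intrinsic contrast
  if (spec$render$blur_sigma_um > 0) {
    img <- .cpp_gaussian_blur(as.vector(img), as.integer(gs),
                              spec$render$blur_sigma_um / vs)
    dim(img) <- gs
  }
  if (spec$render$noise_sd > 0) {
    img <- .with_seed(spec$seed + 1303L,
                      img + rnorm(length(img), 0, spec$render$noise_sd))
    dim(img) <- gs
  }
  intensity_volume(img, vs)
}

#' Cohort specification
#'
#' Describes a set of treatment/time-point groups sharing a base phantom
#' spec, with optional per-group effects: a multiplicative vessel-radius
#' factor applied within a stated distance of the metastases (the
#' anti-angiogenic treatment signature), a lesion-count offset, and a
#' fractional offset on the trabecular rod count.
#'
#' @param groups list of lists, each with `label`, `n` (samples, >= 2), and
#'   optionally `timepoint`, `radius_factor` (in (0, 2]),
#'   `effect_distance_um`, `lesion_offset`, `bone_offset`.
#' @param base a [phantom_spec()] shared by all groups.
#' @param seed cohort seed; per-sample seeds are derived deterministically
#'   from it and the sample index so any sample can be regenerated in
#'   isolation.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(groups, base = phantom_spec(), seed = 1L) {
  stopifnot(inherits(base, "phantom_spec"))
  groups <- lapply(groups, function(g) {
    g <- utils::modifyList(
      list(timepoint = NA_character_, radius_factor = 1,
           effect_distance_um = 700, lesion_offset = 0L, bone_offset = 0),
      g)
    if (is.null(g$label)) stop("each group needs a label")
    if (is.null(g$n) || g$n < 2) stop("each group needs n >= 2 samples")
    if (g$radius_factor <= 0 || g$radius_factor > 2) {
      stop("radius_factor must be in (0, 2] for group ", g$label)
    }
    g
  })
  structure(list(groups = groups, base = base, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of phantoms with injected group effects
#'
#' @param cohort a [cohort_spec()].
#' @return list of samples; each sample is a list with `sample_id`, `group`,
#'   `timepoint`, `labels` and `truth` (as in [generate_labels()]) plus the
#'   per-sample `spec`.
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  samples <- list()
  idx <- 0L
  for (g in cohort$groups) {
    for (i in seq_len(g$n)) {
      idx <- idx + 1L
      spec <- cohort$base
      spec$seed <- .derive_seed(cohort$seed, idx)
      spec$vessels$radius_factor <- g$radius_factor
      spec$vessels$effect_distance_um <- g$effect_distance_um
      spec$metastases$n_lesions <-
        max(0L, spec$metastases$n_lesions + as.integer(g$lesion_offset))
      spec$trabeculae$n_rods <-
        max(0L, round(spec$trabeculae$n_rods * (1 + g$bone_offset)))
      .validate_phantom_spec(spec)
      out <- generate_labels(spec)
      samples[[idx]] <- list(
        sample_id = sprintf("%s_%02d", g$label, i),
        group = g$label,
        timepoint = g$timepoint,
        labels = out$labels,
        truth = out$truth,
        spec = spec)
    }
  }
  samples
}
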