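# Quantitative 3D morphometry of segmented bone/vessel/metastasis volumes:
# total volume (TV) inside the outer bone contour, compartment volumes and
# volume fractions (BV/TV, VV/TV, Me.V/TV), maximal-inscribed-sphere local
# vessel thickness (V.Th), vascular-metastasis interdistance (VMI) and
# distance-restricted (VOI) local metrics.

#' Total-volume (TV) mask: the region inside the outer bone contour
#'
#' The outer contour is realised as a morphological closing of the bone
#' mask with a Euclidean ball followed by 3D hole filling, so the marrow
#' cavity and intra-cortical space count towards TV. Imaged specimens are
#' cut perpendicular to the bone axis, so the axial grid faces are treated
#' as sealed cut planes during hole filling by default: the marrow canal
#' of the open-ended cortical tube still counts as interior. The result is
#' always a superset of the bone mask.
#'
#' @param labels a [label_volume()].
#' @param closing_radius_um closing ball radius in micrometres; default is
#'   10 voxel edges (smallest axis).
#' @param sealed_faces faces treated as specimen-cut planes, see
#'   [fill_holes()]; default `"z"` (the slice axis).
#' @return logical array; `sum(mask) * voxel_volume_um3()` is TV.
#' @export
total_volume_mask <- function(labels, closing_radius_um = NULL,
                              sealed_faces = "z") {
  stopifnot(inherits(labels, "label_volume"))
  vs <- voxel_size(labels)
  if (is.null(closing_radius_um)) closing_radius_um <- 10 * min(vs)
  if (closing_radius_um <= 0) stop("closing_radius_um must be positive")
  bone <- class_mask(labels, "bone")
  if (!any(bone)) stop("empty bone mask: total volume is undefined")
  fill_holes(close_ball(bone, closing_radius_um, vs),
             sealed_faces = sealed_faces)
}

#' Compartment volumes and volume fractions
#'
#' Volumes are measured by counting voxels in each compartment and
#' multiplying by the physical voxel volume; the fractions BV/TV, VV/TV and
#' Me.V/TV are normalised by the total volume.
#'
#' @param labels a [label_volume()].
#' @param tv_mask logical array from [total_volume_mask()]; computed with
#'   default settings when omitted.
#' @return a `morphometry_report` (see [morphometry_report()]) with volume
#'   and ratio fields filled and thickness/distance fields `NA`.
#' @export
compartment_volumes <- function(labels, tv_mask = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(tv_mask)) tv_mask <- total_volume_mask(labels)
  .same_shape(labels, tv_mask, "labels and TV mask")
  vv3 <- voxel_volume_um3(labels)
  n_tv <- sum(tv_mask)
  if (n_tv == 0) stop("TV mask is empty")
  counts <- tabulate(as.vector(labels) + 1L, nbins = 4L)
  n_bone <- counts[2]; n_vessel <- counts[3]; n_met <- counts[4]
  if (n_bone + n_vessel + n_met > n_tv) {
    warning("compartment voxels exceed the TV mask; ",
            "check the closing radius")
  }
  .morphometry_report(
    scope = "global",
    n_tv = n_tv, n_bone = n_bone, n_vessel = n_vessel, n_met = n_met,
    voxel_volume_um3 = vv3)
}

#' Vascular-metastasis interdistance (VMI)
#'
#' The mean, over all vessel voxels, of the Euclidean distance to the
#' nearest metastasis voxel. The per-voxel distance map restricted to the
#' vessel compartment is returned alongside for rendering and for the
#' VOI restriction.
#'
#' @param vessel_mask,metastasis_mask logical 3D arrays of equal shape.
#' @param voxel_size_um voxel edge lengths in micrometres.
#' @return list with `vmi_um` (mean distance; `NA` when undefined),
#'   `undefined` (TRUE when there are no metastasis voxels), and `map`
#'   (distances in micrometres, `NA` outside the vessel mask).
#' @export
vmi <- function(vessel_mask, metastasis_mask, voxel_size_um) {
  vessel_mask <- .check_mask(vessel_mask, "vessel_mask")
  metastasis_mask <- .check_mask(metastasis_mask, "metastasis_mask")
  .same_shape(vessel_mask, metastasis_mask, "vessel and metastasis masks")
  if (!any(vessel_mask)) stop("empty vessel mask: VMI is undefined")
  vs <- .check_voxel_size(voxel_size_um)
  if (!any(metastasis_mask)) {
    map <- array(NA_real_, dim(vessel_mask))
    return(list(vmi_um = NA_real_, undefined = TRUE, map = map))
  }
  d <- distance_transform(metastasis_mask, vs)
  map <- array(NA_real_, dim(vessel_mask))
  map[vessel_mask] <- d[vessel_mask]
  list(vmi_um = mean(d[vessel_mask]), undefined = FALSE, map = map)
}

#' Local thickness by maximal inscribed spheres
#'
#' The thickness at a voxel is the diameter of the largest sphere that fits
#' entirely inside the mask and contains the voxel (the standard local
#' thickness definition in micro-CT bone morphometry). The sphere centred
#' at a voxel extends up to (strictly below) its Euclidean distance to the
#' nearest background voxel centre; its reported inscribed radius is that
#' distance minus half a voxel edge, since the physical boundary lies
#' halfway between the last foreground and first background centres. An
#' isolated voxel therefore has thickness equal to one voxel diameter.
#'
#' @param mask logical 3D array (e.g. the vessel compartment).
#' @param voxel_size_um voxel edge lengths in micrometres.
#' @return list with `map` (thickness in micrometres, 0 outside the mask)
#'   and `mean_um` (V.Th: mean thickness over mask voxels).
#' @export
local_thickness <- function(mask, voxel_size_um) {
  mask <- .check_mask(mask)
  if (!any(mask)) stop("empty mask: local thickness is undefined")
  vs <- .check_voxel_size(voxel_size_um)
  th <- .cpp_local_thickness(as.vector(mask), .as_dim(mask), vs)
  dim(th) <- dim(mask)
  list(map = th, mean_um = mean(th[mask]))
}

#' Distance-restricted volume of interest (VOI)
#'
#' Selects the voxels of the TV mask whose Euclidean distance to the
#' metastasis compartment is strictly below a threshold, e.g. the region
#' within 700 um of the metastases.
#'
#' @param metastasis_mask logical 3D array; must be nonempty.
#' @param tv_mask logical array from [total_volume_mask()].
#' @param threshold_um distance threshold in micrometres (strict `<`).
#' @param voxel_size_um voxel edge lengths in micrometres.
#' @return logical array: `distance < threshold_um & tv_mask`.
#' @export
voi_mask <- function(metastasis_mask, tv_mask, threshold_um, voxel_size_um) {
  metastasis_mask <- .check_mask(metastasis_mask, "metastasis_mask")
  tv_mask <- .check_mask(tv_mask, "tv_mask")
  .same_shape(metastasis_mask, tv_mask, "metastasis and TV masks")
  if (!any(metastasis_mask)) {
    stop("empty metastasis mask: the VOI is undefined")
  }
  if (threshold_um <= 0) stop("threshold_um must be positive")
  d <- distance_transform(metastasis_mask, voxel_size_um)
  out <- (unclass(d) < threshold_um) & tv_mask
  dim(out) <- dim(tv_mask)
  out
}

#' VOI-restricted local metrics
#'
#' Local VV/TV is the vessel voxel count inside the VOI divided by the VOI
#' voxel count (the VOI being a subset of the TV mask). Local V.Th is the
#' mean of the thickness map sampled at vessel voxels inside the VOI; the
#' thickness map is computed on the full vessel mask so inscribed spheres
#' are not truncated at the VOI boundary.
#'
#' @param labels a [label_volume()].
#' @param voi logical array from [voi_mask()].
#' @param thickness_map optional precomputed map from [local_thickness()]
#'   on the full vessel mask; computed when omitted.
#' @param threshold_um threshold used to build `voi` (recorded in the
#'   report's scope tag).
#' @return a `morphometry_report` with scope `"voi"`; `vth_um` is `NA` with
#'   `vth_undefined = TRUE` when the VOI contains no vessel voxels.
#' @export
local_metrics <- function(labels, voi, thickness_map = NULL,
                          threshold_um = NA_real_) {
  stopifnot(inherits(labels, "label_volume"))
  voi <- .check_mask(voi, "voi")
  .same_shape(labels, voi, "labels and VOI")
  if (!any(voi)) stop("empty VOI")
  vessel <- class_mask(labels, "vessel")
  vv3 <- voxel_volume_um3(labels)
  n_tv <- sum(voi)
  sel <- vessel & voi
  n_vessel <- sum(sel)
  if (n_vessel == 0) {
    vth <- NA_real_
    vth_undef <- TRUE
  } else {
    if (is.null(thickness_map)) {
      thickness_map <- local_thickness(vessel, voxel_size(labels))$map
    }
    .same_shape(labels, thickness_map, "labels and thickness map")
    vth <- mean(thickness_map[sel])
    vth_undef <- FALSE
  }
  rep <- .morphometry_report(
    scope = "voi",
    n_tv = n_tv,
    n_bone = sum(class_mask(labels, "bone") & voi),
    n_vessel = n_vessel,
    n_met = sum(class_mask(labels, "metastasis") & voi),
    voxel_volume_um3 = vv3)
  rep$threshold_um <- threshold_um
  rep$vth_um <- vth
  rep$vth_undefined <- vth_undef
  rep
}

#' Full morphometry report for one sample
#'
#' Convenience wrapper computing TV, the compartment volumes and fractions,
#' mean local vessel thickness (V.Th) and the vascular-metastasis
#' interdistance (VMI) in one call.
#'
#' @param labels a [label_volume()].
#' @param closing_radius_um TV closing radius, see [total_volume_mask()].
#' @param tv_mask optional precomputed TV mask.
#' @return a `morphometry_report`: a list with voxel counts (`n_tv`,
#'   `n_bone`, `n_vessel`, `n_met`), volumes in cubic micrometres (`tv_um3`,
#'   `bv_um3`, `vv_um3`, `mev_um3`), fractions (`bvtv`, `vvtv`, `mevtv`),
#'   `vth_um`, `vmi_um` and undefined-value flags. Use `as.data.frame()` for
#'   a one-row table.
#' @export
morphometry_report <- function(labels, closing_radius_um = NULL,
                               tv_mask = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(tv_mask)) tv_mask <- total_volume_mask(labels, closing_radius_um)
  rep <- compartment_volumes(labels, tv_mask)
  vs <- voxel_size(labels)
  vessel <- class_mask(labels, "vessel")
  met <- class_mask(labels, "metastasis")
  if (any(vessel)) {
    rep$vth_um <- local_thickness(vessel, vs)$mean_um
    rep$vth_undefined <- FALSE
    v <- vmi(vessel, met, vs)
    rep$vmi_um <- v$vmi_um
    rep$vmi_undefined <- v$undefined
  } else {
    rep$vth_um <- NA_real_
    rep$vth_undefined <- TRUE
    rep$vmi_um <- NA_real_
    rep$vmi_undefined <- TRUE
  }
  rep
}

.morphometry_report <- function(scope, n_tv, n_bone, n_vessel, n_met,
                                voxel_volume_um3) {
  structure(list(
    scope = scope,
    threshold_um = NA_real_,
    n_tv = n_tv, n_bone = n_bone, n_vessel = n_vessel, n_met = n_met,
    tv_um3 = n_tv * voxel_volume_um3,
    bv_um3 = n_bone * voxel_volume_um3,
    vv_um3 = n_vessel * voxel_volume_um3,
    mev_um3 = n_met * voxel_volume_um3,
    bvtv = n_bone / n_tv,
    vvtv = n_vessel / n_tv,
    mevtv = n_met / n_tv,
    vth_um = NA_real_, vth_undefined = NA,
    vmi_um = NA_real_, vmi_undefined = NA
  ), class = "morphometry_report")
}

#' @export
as.data.frame.morphometry_report <- function(x, ...) {
  data.frame(scope = x$scope, threshold_um = x$threshold_um,
             n_tv = x$n_tv, n_bone = x$n_bone, n_vessel = x$n_vessel,
             n_met = x$n_met,
             tv_um3 = x$tv_um3, bv_um3 = x$bv_um3, vv_um3 = x$vv_um3,
             mev_um3 = x$mev_um3,
             bvtv = x$bvtv, vvtv = x$vvtv, mevtv = x$mevtv,
             vth_um = x$vth_um, vmi_um = x$vmi_um,
             stringsAsFactors = FALSE)
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("<morphometry report, scope %s%s>\n", x$scope,
              if (!is.na(x$threshold_um))
                sprintf(" (< %g um)", x$threshold_um) else ""))
  cat(sprintf("  TV %.4g mm3 | BV/TV %.4f | VV/TV %.4f | Me.V/TV %.4f\n",
              x$tv_um3 / 1e9, x$bvtv, x$vvtv, x$mevtv))
  cat(sprintf("  V.Th %s um | VMI %s um\n",
              if (is.na(x$vth_um)) "undefined" else sprintf("%.2f", x$vth_um),
              if (is.na(x$vmi_um)) "undefined" else sprintf("%.1f", x$vmi_um)))
  invisible(x)
}
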