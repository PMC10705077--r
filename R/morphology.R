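# Binary 3D morphology built on the exact Euclidean distance transform:
# dilation/erosion with a true Euclidean ball, closing, border-connected
# hole filling and connected-component filtering. These are the building
# blocks for the total-volume (TV) contour and the cavity-based metastasis
# inference.

.as_dim <- function(x) as.integer(dim(x))

#' Exact Euclidean distance transform
#'
#' Distance (in micrometres, voxel centre to voxel centre) from every voxel
#' to the nearest voxel of a reference set, honouring anisotropic voxel
#' sizes. Computed with the separable lower-envelope algorithm, which is
#' exact for the squared Euclidean metric.
#'
#' @param reference_mask logical 3D array; the set distances are measured to.
#' @param voxel_size_um voxel edge lengths (scalar or length 3, micrometres).
#' @return a `distance_map`: numeric array of distances in micrometres,
#'   zero exactly on the reference set.
#' @export
distance_transform <- function(reference_mask, voxel_size_um) {
  reference_mask <- .check_mask(reference_mask, "reference_mask")
  vs <- .check_voxel_size(voxel_size_um)
  if (!any(reference_mask)) stop("reference mask is empty")
  d2 <- .cpp_edt_sq(as.vector(reference_mask), .as_dim(reference_mask), vs)
  d <- sqrt(d2)
  dim(d) <- dim(reference_mask)
  structure(d, voxel_size_um = vs,
            class = c("distance_map", "array"))
}

# Squared-distance helper used internally (no class wrapper, allows empty
# reference which yields all-Inf).
.edt_sq <- function(mask, vs) {
  d2 <- .cpp_edt_sq(as.vector(mask), .as_dim(mask), vs)
  dim(d2) <- dim(mask)
  d2
}

#' Binary dilation/erosion/closing with a Euclidean ball
#'
#' The structuring element is the set of voxel-centre offsets with Euclidean
#' norm at most `radius_um`, evaluated through the exact distance transform
#' so anisotropic voxels are handled correctly.
#'
#' @param mask logical 3D array.
#' @param radius_um ball radius in micrometres.
#' @param voxel_size_um voxel edge lengths.
#' @return logical array of the same shape.
#' @export
dilate_ball <- function(mask, radius_um, voxel_size_um) {
  mask <- .check_mask(mask)
  vs <- .check_voxel_size(voxel_size_um)
  if (!any(mask)) return(mask)
  out <- .edt_sq(mask, vs) <= radius_um^2
  dim(out) <- dim(mask)
  out
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, radius_um, voxel_size_um) {
  mask <- .check_mask(mask)
  vs <- .check_voxel_size(voxel_size_um)
  if (all(mask)) return(mask)
  out <- mask & (.edt_sq(!mask, vs) > radius_um^2)
  dim(out) <- dim(mask)
  out
}

#' @rdname dilate_ball
#' @details By default `close_ball` evaluates dilation and erosion on a
#'   grid padded by the ball radius on every side before cropping back, so
#'   the result is the true (unbounded-domain) Euclidean closing: a convex
#'   solid closes to itself and the result is always a superset of the
#'   input. With `bounded = TRUE` the operation is restricted to the grid
#'   (everything beyond the border is treated as unknown rather than
#'   background), which keeps structures cut by the grid faces closed.
#' @param bounded logical; see Details.
#' @export
close_ball <- function(mask, radius_um, voxel_size_um, bounded = FALSE) {
  mask <- .check_mask(mask)
  vs <- .check_voxel_size(voxel_size_um)
  if (!any(mask)) return(mask)
  if (bounded) {
    dil <- dilate_ball(mask, radius_um, vs)
    return(erode_ball(dil, radius_um, vs) | mask)
  }
  pad <- ceiling(radius_um / vs) + 1
  d <- dim(mask)
  big <- array(FALSE, d + 2 * pad)
  idx <- lapply(1:3, function(a) seq(pad[a] + 1, pad[a] + d[a]))
  big[idx[[1]], idx[[2]], idx[[3]]] <- mask
  dil <- .edt_sq(big, vs) <= radius_um^2
  dim(dil) <- dim(big)
  clo <- dil & (.edt_sq(!dil, vs) > radius_um^2)
  dim(clo) <- dim(big)
  out <- clo[idx[[1]], idx[[2]], idx[[3]]] | mask
  out
}

#' Fill internal cavities of a binary mask
#'
#' Background voxels not reachable from the grid border by 6-connected
#' steps are added to the mask. Faces named in `sealed_faces` do not seed
#' the border flood: they behave as closed specimen-cut planes, so a
#' structure truncated by such a face (e.g. the marrow canal of a cut
#' bone) still counts as enclosed.
#'
#' @param mask logical 3D array.
#' @param sealed_faces subset of `c("x", "y", "z")`; both faces of each
#'   named axis are sealed.
#' @return logical array with cavities filled.
#' @export
fill_holes <- function(mask, sealed_faces = character()) {
  mask <- .check_mask(mask)
  sealed <- c("x", "y", "z") %in% sealed_faces
  out <- .cpp_fill_holes(as.vector(mask), .as_dim(mask), sealed)
  dim(out) <- dim(mask)
  out
}

#' Label connected components
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (face) or 26 (face/edge/vertex) neighbourhood.
#' @return integer array; 0 outside the mask, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- .check_mask(mask)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  out <- .cpp_label_components(as.vector(mask), .as_dim(mask),
                               as.integer(connectivity))
  dim(out) <- dim(mask)
  out
}

#' Remove connected components below a minimum voxel count
#'
#' @inheritParams label_components
#' @param min_voxels components with fewer voxels are dropped.
#' @return logical array.
#' @export
filter_small_components <- function(mask, min_voxels, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (min_voxels <= 1 || max(lab) == 0L) return(mask & TRUE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  out <- array(lab %in% keep, dim = dim(mask))
  out
}
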