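# 3D volume containers. Arrays are stored in R's native column-major order
# with dim = c(nx, ny, nz): the first index runs along x within a slice and
# the third index is the slice (z). Files are read/written slice-by-slice
# along z. Voxel sizes are physical edge lengths in micrometres, per axis.

#' Construct a 3D label volume
#'
#' A label volume assigns each voxel to one of four compartments:
#' 0 background, 1 bone, 2 vessel, 3 metastasis. It is the central currency
#' of the analysis pipeline: morphometry, Dice evaluation and the
#' volume-of-interest restriction all operate on label volumes.
#'
#' @param data 3D integer array (or numeric holding whole numbers), axis
#'   order `[x, y, z]` with z the slice index.
#' @param voxel_size_um voxel edge lengths in micrometres; scalar or
#'   length-3 `(x, y, z)`. Anisotropic sizes are honoured by all
#'   distance-based measures.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_size_um) {
  data <- .check_grid(data)
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), 0:3)
  if (length(bad) > 0) {
    stop("unknown class id(s) in label volume: ", paste(bad, collapse = ", "),
         " (vocabulary is 0 background, 1 bone, 2 vessel, 3 metastasis)")
  }
  structure(data,
            voxel_size_um = .check_voxel_size(voxel_size_um),
            class = c("label_volume", "ov_volume", "array"))
}

#' Construct a 3D grayscale intensity volume
#'
#' Emulates a reconstructed attenuation volume; input to the baseline
#' segmenter.
#'
#' @inheritParams label_volume
#' @return object of class `intensity_volume`.
#' @export
intensity_volume <- function(data, voxel_size_um) {
  data <- .check_grid(data)
  storage.mode(data) <- "double"
  structure(data,
            voxel_size_um = .check_voxel_size(voxel_size_um),
            class = c("intensity_volume", "ov_volume", "array"))
}

#' Voxel size of a volume
#' @param vol a volume or any array carrying a `voxel_size_um` attribute.
#' @return numeric length 3, micrometres per axis.
#' @export
voxel_size <- function(vol) {
  vs <- attr(vol, "voxel_size_um")
  if (is.null(vs)) stop("object carries no voxel size")
  vs
}

#' Physical volume of one voxel in cubic micrometres
#' @inheritParams voxel_size
#' @export
voxel_volume_um3 <- function(vol) prod(voxel_size(vol))

#' Extract a compartment mask from a label volume
#' @param labels a [label_volume()].
#' @param class_id integer class id or one of `"bone"`, `"vessel"`,
#'   `"metastasis"`, `"background"`.
#' @return logical array of the same shape.
#' @export
class_mask <- function(labels, class_id) {
  if (is.character(class_id)) {
    class_id <- switch(class_id,
                       background = 0L, bone = 1L, vessel = 2L,
                       metastasis = 3L,
                       stop("unknown class name: ", class_id))
  }
  m <- unclass(labels) == class_id
  dim(m) <- dim(labels)
  m
}

#' @export
print.ov_volume <- function(x, ...) {
  d <- dim(x)
  vs <- voxel_size(x)
  cat(sprintf("<%s> %d x %d x %d voxels, voxel size %s um\n",
              class(x)[1], d[1], d[2], d[3],
              paste(format(vs), collapse = " x ")))
  if (inherits(x, "label_volume")) {
    counts <- tabulate(as.vector(x) + 1L, nbins = 4L)
    cat(sprintf("  background %d | bone %d | vessel %d | metastasis %d\n",
                counts[1], counts[2], counts[3], counts[4]))
  }
  invisible(x)
}

.check_grid <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("volume data must be a 3D array")
  }
  if (any(dim(data) < 2L)) stop("volume must have at least 2 voxels per axis")
  data
}

.check_voxel_size <- function(vs) {
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  if (length(vs) != 3L || !is.numeric(vs) || any(!is.finite(vs)) || any(vs <= 0)) {
    stop("voxel_size_um must be a positive scalar or length-3 numeric")
  }
  as.numeric(vs)
}

.check_mask <- function(mask, name = "mask") {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L) {
    stop(name, " must be a 3D logical array")
  }
  if (!is.logical(mask)) {
    storage.mode(mask) <- "logical"
  }
  if (anyNA(mask)) stop(name, " contains NA")
  mask
}

.same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop("shape mismatch: ", what, " have dimensions ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}

# Run code with a temporarily-seeded RNG, restoring the caller's state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-sample seed derived from a cohort seed and sample index;
# kept below 2^31 so it is a valid R integer seed.
.derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) %% 100000) * 20011 +
               as.numeric(index) * 7919) %% 2147483629L
}
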