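# Volume I/O: multi-page TIFF stacks, MetaImage (.mha), NIfTI and raw +
# JSON sidecar. Arrays are stored [x, y, z] with z the slice index; files
# are written slice-by-slice along z. Voxel sizes travel in the image
# header where the format has one (MetaImage ElementSpacing, NIfTI pixdim,
# both in micrometres here) and in a JSON sidecar otherwise.

.detect_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.tiff?$", lp)) return("tiff")
  if (grepl("\\.mha$", lp)) return("mha")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.raw$", lp)) return("raw")
  stop("cannot infer volume format from path: ", path)
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume to disk
#'
#' Supported formats (chosen from the file extension unless `format` is
#' given): multi-page TIFF (`.tif`/`.tiff`; 8-bit for labels, 32-bit float
#' for intensities; voxel size in a JSON sidecar), MetaImage (`.mha`,
#' uncompressed, voxel size in `ElementSpacing`), NIfTI (`.nii`/`.nii.gz`,
#' voxel size in `pixdim`, micrometres), and raw little-endian (`.raw` plus
#' a JSON sidecar carrying dimensions, type and voxel size).
#'
#' @param vol a [label_volume()] or [intensity_volume()].
#' @param path output file path.
#' @param format one of `"auto"`, `"tiff"`, `"mha"`, `"nifti"`, `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = "auto") {
  stopifnot(inherits(vol, "ov_volume"))
  if (format == "auto") format <- .detect_format(path)
  vs <- voxel_size(vol)
  d <- dim(vol)
  is_label <- inherits(vol, "label_volume")
  arr <- unclass(vol)
  attributes(arr) <- list(dim = d)
  switch(format,
    tiff = {
      # tiff stores values in [0,1]: labels are scaled by 255, intensities
      # mapped affinely with the mapping recorded in the sidecar
      if (is_label) {
        offset <- 0; slope <- 255
      } else {
        rng <- range(arr)
        offset <- rng[1]
        slope <- max(rng[2] - rng[1], .Machine$double.eps)
      }
      slices <- lapply(seq_len(d[3]), function(k) (arr[, , k] - offset) / slope)
      tiff::writeTIFF(slices, path,
                      bits.per.sample = if (is_label) 8L else 32L,
                      compression = "none", reduce = FALSE)
      jsonlite::write_json(
        list(voxel_size_um = vs, type = if (is_label) "label" else "intensity",
             offset = offset, slope = slope),
        .sidecar_path(path), auto_unbox = FALSE, digits = NA)
    },
    mha = {
      con <- file(path, "wb")
      on.exit(close(con))
      header <- paste0(
        "ObjectType = Image\n",
        "NDims = 3\n",
        "BinaryData = True\n",
        "BinaryDataByteOrderMSB = False\n",
        "DimSize = ", paste(d, collapse = " "), "\n",
        "ElementSpacing = ", paste(format(vs, scientific = FALSE),
                                   collapse = " "), "\n",
        "ElementType = ", if (is_label) "MET_SHORT" else "MET_DOUBLE", "\n",
        "ElementDataFile = LOCAL\n")
      writeChar(header, con, eos = NULL)
      if (is_label) {
        writeBin(as.integer(arr), con, size = 2L, endian = "little")
      } else {
        writeBin(as.numeric(arr), con, size = 8L, endian = "little")
      }
    },
    nifti = {
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- vs
      RNifti::writeNifti(img, path)
    },
    raw = {
      con <- file(path, "wb")
      if (is_label) {
        writeBin(as.integer(arr), con, size = 4L, endian = "little")
      } else {
        writeBin(as.numeric(arr), con, size = 8L, endian = "little")
      }
      close(con)
      jsonlite::write_json(
        list(dim = d, voxel_size_um = vs,
             type = if (is_label) "label" else "intensity"),
        .sidecar_path(path), auto_unbox = FALSE, digits = NA)
    },
    stop("unsupported format: ", format)
  )
  invisible(path)
}

#' Read a volume from disk
#'
#' Counterpart of [write_volume()]. The voxel size is taken from the image
#' header (MetaImage, NIfTI) or JSON sidecar (TIFF, raw) when present, else
#' from `voxel_size_um`; an error is raised when neither is available.
#' Label volumes are validated against the class vocabulary (0 background,
#' 1 bone, 2 vessel, 3 metastasis); unknown ids are an error.
#'
#' @param path file path.
#' @param type `"auto"` (label when the payload is integer-valued),
#'   `"label"` or `"intensity"`.
#' @param voxel_size_um fallback voxel size when the file carries none.
#' @param format format override, see [write_volume()].
#' @return a [label_volume()] or [intensity_volume()].
#' @export
read_volume <- function(path, type = "auto", voxel_size_um = NULL,
                        format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .detect_format(path)
  vs <- NULL
  side_type <- NULL
  arr <- switch(format,
    tiff = {
      slices <- tiff::readTIFF(path, all = TRUE)
      a <- array(unlist(slices),
                 dim = c(dim(slices[[1]])[1], dim(slices[[1]])[2],
                         length(slices)))
      sp <- .sidecar_path(path)
      if (file.exists(sp)) {
        side <- jsonlite::read_json(sp, simplifyVector = TRUE)
        vs <- side$voxel_size_um
        side_type <- side$type
        if (identical(side_type, "label")) {
          a <- round(a * 255)
        } else if (!is.null(side$slope)) {
          a <- side$offset + a * side$slope
        }
      }
      a
    },
    mha = .read_mha(path, function(spacing) vs <<- spacing),
    nifti = {
      img <- RNifti::readNifti(path)
      vs <- RNifti::pixdim(img)
      a <- as.array(img)
      attributes(a) <- list(dim = dim(a))
      a
    },
    raw = {
      sp <- .sidecar_path(path)
      if (!file.exists(sp)) stop("raw volume needs a JSON sidecar: ", sp)
      side <- jsonlite::read_json(sp, simplifyVector = TRUE)
      vs <- side$voxel_size_um
      side_type <- side$type
      con <- file(path, "rb")
      on.exit(close(con))
      n <- prod(side$dim)
      a <- if (identical(side$type, "label")) {
        readBin(con, "integer", n, size = 4L, endian = "little")
      } else {
        readBin(con, "numeric", n, size = 8L, endian = "little")
      }
      dim(a) <- side$dim
      a
    },
    stop("unsupported format: ", format)
  )
  if (is.null(vs)) vs <- voxel_size_um
  if (is.null(vs)) {
    stop("no voxel size in header or sidecar for ", path,
         "; pass voxel_size_um")
  }
  if (type == "auto") {
    type <- if (!is.null(side_type)) side_type
            else if (all(arr == round(arr)) && max(arr) <= 3 && min(arr) >= 0)
              "label" else "intensity"
  }
  if (type == "label") {
    if (max(abs(arr - round(arr))) > 1e-6) {
      stop("non-integer data in a label volume: ", path)
    }
    label_volume(round(arr), vs)
  } else {
    intensity_volume(arr, vs)
  }
}

# Minimal MetaImage reader for the uncompressed LOCAL layout written by
# write_volume.
.read_mha <- function(path, set_spacing) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- list()
  repeat {
    line <- character(0)
    repeat { # read one header line byte-wise (payload follows immediately)
      ch <- readBin(con, "raw", 1L)
      if (length(ch) == 0) stop("corrupt MetaImage header: ", path)
      if (ch == as.raw(10L)) break
      line <- c(line, rawToChar(ch))
    }
    line <- paste(line, collapse = "")
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("corrupt MetaImage header line: ", line)
    header[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  d <- as.integer(strsplit(header$DimSize, " ")[[1]])
  if (length(d) != 3 || anyNA(d)) stop("corrupt MetaImage DimSize")
  set_spacing(as.numeric(strsplit(header$ElementSpacing, " ")[[1]]))
  n <- prod(d)
  arr <- switch(header$ElementType,
    MET_SHORT = readBin(con, "integer", n, size = 2L, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8L, endian = "little"),
    MET_FLOAT = readBin(con, "numeric", n, size = 4L, endian = "little"),
    MET_UCHAR = readBin(con, "integer", n, size = 1L, signed = FALSE,
                        endian = "little"),
    stop("unsupported MetaImage ElementType: ", header$ElementType))
  if (length(arr) != n) stop("truncated MetaImage payload: ", path)
  dim(arr) <- d
  arr
}
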