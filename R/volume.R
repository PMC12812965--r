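#' Volumetric image container
#'
#' A `volume_image` holds a 3D scalar intensity grid together with its voxel
#' spacing (mm) and a patient identifier. It is the unit of currency of the
#' imaging branch: raw scans, masked scans and resampled scans are all
#' `volume_image` objects. Axis order is (x, y, z) in 0-based voxel-index
#' space; spacing is carried as metadata.
#'
#' @param data 3D numeric array of intensities. Must contain no `NaN`.
#' @param spacing numeric length-3 vector of voxel sizes in mm.
#' @param id patient identifier string.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), id = "unknown") {
  assert_that(is.array(data) && length(dim(data)) == 3,
              "volume data must be a 3D array", "gliofuse_dimension_error")
  assert_that(all(dim(data) >= 1), "all volume dimensions must be >= 1",
              "gliofuse_dimension_error")
  assert_that(!anyNA(data), "volume contains NaN/NA intensities",
              "gliofuse_value_error")
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be 3 positive values")
  structure(list(data = data, spacing = as.numeric(spacing), id = as.character(id)),
            class = "volume_image")
}

#' Binary brain mask paired with a volume
#'
#' @param data 3D array with values in \{0, 1\} (logical or numeric).
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data) {
  assert_that(is.array(data) && length(dim(data)) == 3,
              "mask data must be a 3D array", "gliofuse_dimension_error")
  d <- data
  storage.mode(d) <- "double"
  assert_that(all(d %in% c(0, 1)), "mask values must be 0 or 1",
              "gliofuse_value_error")
  structure(list(data = d), class = "brain_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s  dims %s  spacing %s mm  range [%.3g, %.3g]\n",
              x$id, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> dims %s  brain voxels %d\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Read a NIfTI volume from disk
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param id patient identifier; defaults to the file stem.
#' @return A [volume_image].
#' @export
read_nifti_volume <- function(path, id = NULL) {
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  if (length(dim(dat)) > 3) dat <- array(dat, dim = dim(dat)[1:3])
  if (anyNA(dat)) {
    stop_gliofuse(sprintf("NIfTI volume '%s' contains NaN voxels", path),
                  "gliofuse_value_error")
  }
  sp <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
  if (length(sp) < 3 || anyNA(sp) || any(sp <= 0)) sp <- c(1, 1, 1)
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  volume_image(dat, spacing = sp, id = id)
}

#' Write a volume (or mask) to NIfTI
#'
#' @param volume a [volume_image] or [brain_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path) {
  if (inherits(volume, "brain_mask")) {
    dat <- volume$data
    storage.mode(dat) <- "integer"
    img <- RNifti::asNifti(dat)
  } else {
    img <- RNifti::asNifti(volume$data)
    RNifti::pixdim(img) <- volume$spacing
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI brain mask
#'
#' Any non-zero voxel is treated as brain.
#'
#' @param path path to the mask file.
#' @return A [brain_mask].
#' @export
read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  if (length(dim(dat)) > 3) dat <- array(dat, dim = dim(dat)[1:3])
  brain_mask((dat != 0) * 1)
}
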