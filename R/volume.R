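#' Labeled CT volume
#'
#' A `labeled_volume` couples a 3D grid of Hounsfield-unit intensities with an
#' aligned integer region-of-interest (ROI) mask and the voxel spacing in mm.
#' Mask value 0 is background; values 1-4 are the four liver-region tissue
#' classes (normal liver, benign cyst, hemangioma, metastasis).
#'
#' @param intensities 3D numeric array of intensities (HU).
#' @param spacing Numeric length-3 voxel spacing in mm (x, y, z).
#' @param mask 3D integer array of the same dimensions as `intensities`;
#'   values must lie in `{0, 1, 2, 3, 4}`.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(intensities, spacing, mask = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3) {
    stop("`intensities` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- array(0L, dim(intensities))
  }
  if (!identical(dim(mask), dim(intensities))) {
    stop("`mask` and `intensities` must have identical dimensions", call. = FALSE)
  }
  storage.mode(mask) <- "integer"
  bad <- setdiff(unique(as.vector(mask)), 0:4)
  if (length(bad) > 0) {
    stop("mask values must be in {0,1,2,3,4}; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(intensities = intensities, spacing = spacing, mask = mask),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  labs <- sort(setdiff(unique(as.vector(x$mask)), 0L))
  cat(sprintf("  intensity range [%.1f, %.1f] HU; ROI labels: %s\n",
              min(x$intensities), max(x$intensities),
              if (length(labs)) paste(labs, collapse = ", ") else "none"))
  invisible(x)
}

#' Write a labeled volume as a NIfTI pair
#'
#' Writes `<prefix>_image.nii.gz` and `<prefix>_mask.nii.gz` with voxel spacing
#' recorded in the header.
#'
#' @param volume A [labeled_volume()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths written.
#' @export
write_volume <- function(volume, prefix) {
  stopifnot(inherits(volume, "labeled_volume"))
  img <- RNifti::asNifti(volume$intensities, pixdim = volume$spacing)
  msk <- RNifti::asNifti(volume$mask, pixdim = volume$spacing)
  paths <- paste0(prefix, c("_image.nii.gz", "_mask.nii.gz"))
  RNifti::writeNifti(img, paths[1])
  RNifti::writeNifti(msk, paths[2])
  invisible(paths)
}

#' Read a labeled volume from a NIfTI pair
#'
#' @param prefix Path prefix used by [write_volume()].
#' @return A [labeled_volume()].
#' @export
read_volume <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, "_image.nii.gz"))
  msk <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  spacing <- RNifti::pixdim(img)[1:3]
  labeled_volume(array(as.numeric(img), dim(img)), spacing,
                 array(as.integer(round(as.numeric(msk))), dim(msk)))
}
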