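
resample_array <- function(arr, out_dims, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  out_dims <- as.integer(out_dims)
  if (identical(dim(arr), out_dims)) return(arr)
  vals <- cpp_resample3d(as.numeric(arr), dim(arr), out_dims,
                         if (mode == "nearest") 1L else 0L)
  array(vals, out_dims)
}

#' Standardize a volume's geometry
#'
#' Reproduces the image standardization chain: resample to isotropic voxels
#' (linear interpolation for intensities, nearest-neighbour for the mask),
#' crop to the tight bounding box of above-threshold voxels (removing empty
#' background), then resample to a fixed grid shape.
#'
#' @param volume A [labeled_volume()].
#' @param target_spacing Intermediate isotropic spacing in mm.
#' @param target_shape Final grid dimensions. The default mirrors a common
#'   paired-training resolution of 256 x 256 in-plane with 246 axial voxels.
#' @param crop_threshold Voxels above this HU value count as foreground
#'   (default -500, air vs object).
#' @return A [labeled_volume()] with spacing equal to the effective voxel
#'   size of the cropped field of view divided by `target_shape`.
#' @export
standardize_volume <- function(volume, target_spacing = c(1, 1, 1),
                               target_shape = c(256, 256, 246),
                               crop_threshold = -500) {
  stopifnot(inherits(volume, "labeled_volume"))
  iso_dims <- pmax(1L, as.integer(round(dim(volume$intensities) *
                                          volume$spacing / target_spacing)))
  inten <- resample_array(volume$intensities, iso_dims, "linear")
  mask <- resample_array(volume$mask, iso_dims, "nearest")

  fg <- which(inten > crop_threshold, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    stop("crop error: no foreground voxels above threshold ", crop_threshold,
         call. = FALSE)
  }
  lo <- apply(fg, 2, min)
  hi <- apply(fg, 2, max)
  inten <- inten[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  out_spacing <- target_spacing * dim(inten) / target_shape
  inten <- resample_array(inten, target_shape, "linear")
  mask <- resample_array(mask, target_shape, "nearest")
  labeled_volume(inten, out_spacing, array(as.integer(round(mask)), dim(mask)))
}

#' Clip volume intensities to a Hounsfield window
#'
#' Every intensity v is replaced by `min(max(v, lo), hi)`; the mask is
#' untouched. The default window `[-45, 125]` HU brackets the abdominal
#' soft-tissue contrast used throughout the analysis.
#'
#' @param volume A [labeled_volume()].
#' @param lo,hi Window bounds in HU, `lo < hi`.
#' @return A clipped [labeled_volume()].
#' @export
clip_intensity <- function(volume, lo = -45, hi = 125) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("invalid range: require lo < hi", call. = FALSE)
  }
  volume$intensities <- pmin(pmax(volume$intensities, lo), hi)
  volume
}

#' Relabel ROI mask values
#'
#' Replaces each nonzero label by its mapped value; background 0 is always
#' preserved and per-class voxel counts are conserved.
#'
#' @param mask 3D integer array.
#' @param mapping Named vector or list, `old label -> new label` (names are
#'   old labels).
#' @return Relabeled integer array.
#' @export
#' @examples
#' m <- array(c(0L, 5L, 9L, 5L), c(2, 2, 1))
#' relabel_rois(m, c("5" = 1, "9" = 4))
relabel_rois <- function(mask, mapping) {
  stopifnot(is.array(mask))
  mapping <- unlist(mapping)
  old <- as.integer(names(mapping))
  if (any(is.na(old))) stop("mapping must be named by old labels", call. = FALSE)
  present <- setdiff(unique(as.vector(mask)), 0L)
  unmapped <- setdiff(present, old)
  if (length(unmapped)) {
    stop("unknown label(s) with no mapping entry: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  out <- mask
  for (i in seq_along(old)) {
    out[mask == old[i]] <- as.integer(mapping[i])
  }
  storage.mode(out) <- "integer"
  out
}
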