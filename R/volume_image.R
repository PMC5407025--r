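#' 3D scalar image with acquisition geometry
#'
#' The unit every pipeline stage consumes and produces: a 3D intensity array
#' plus voxel spacing and the through-plane slice geometry (acquired slice
#' thickness and interslice gap; their sum is the centre-to-centre spacing
#' along the slice axis).
#'
#' @param data 3D numeric array of intensities (finite).
#' @param voxel_size_mm centre-to-centre voxel spacing per axis (3 values, mm).
#' @param slice_axis index of the through-plane axis (default 3).
#' @param slice_thickness_mm acquired slice thickness (mm).
#' @param slice_gap_mm unacquired gap between slices (mm, >= 0).
#' @param timepoint_label optional label, e.g. "48h" or "9d".
#' @return object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size_mm, slice_axis = 3L,
                         slice_thickness_mm = voxel_size_mm[slice_axis],
                         slice_gap_mm = 0, timepoint_label = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("volume_image: intensities must be finite")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("volume_image: voxel_size_mm must be 3 positive values")
  }
  slice_axis <- as.integer(slice_axis)
  stopifnot(slice_axis %in% 1:3)
  if (slice_thickness_mm <= 0) stop("volume_image: slice_thickness_mm must be > 0")
  if (slice_gap_mm < 0) stop("volume_image: slice_gap_mm must be >= 0")
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, slice_axis = slice_axis,
         slice_thickness_mm = slice_thickness_mm, slice_gap_mm = slice_gap_mm,
         timepoint_label = timepoint_label),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d voxels @ %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3]))
  cat(sprintf("  slice axis %d: thickness %.3g mm, gap %.3g mm%s\n",
              x$slice_axis, x$slice_thickness_mm, x$slice_gap_mm,
              if (is.null(x$timepoint_label)) "" else
                paste0(", timepoint ", x$timepoint_label)))
  invisible(x)
}

# replace the intensity array, keeping geometry
with_data <- function(vol, data) {
  vol$data <- data
  vol
}

in_plane_axes <- function(vol) setdiff(1:3, vol$slice_axis)

# area of one voxel face in the acquired slice plane
in_plane_area_mm2 <- function(vol) {
  prod(vol$voxel_size_mm[in_plane_axes(vol)])
}

voxel_volume_mm3 <- function(vol) prod(vol$voxel_size_mm)

#' Write a volume to NIfTI
#'
#' @param vol a [volume_image()] (logical arrays are written as 0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  data <- vol$data
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' Voxel spacing is taken from the NIfTI header; the slice thickness/gap
#' split is acquisition metadata NIfTI does not carry, so it is supplied by
#' the caller (defaults: thickness = through-plane spacing, no gap).
#'
#' @param path NIfTI file.
#' @param slice_axis through-plane axis (default 3).
#' @param slice_thickness_mm,slice_gap_mm slice geometry overrides.
#' @param timepoint_label optional label.
#' @return a [volume_image()].
#' @export
read_volume <- function(path, slice_axis = 3L, slice_thickness_mm = NULL,
                        slice_gap_mm = 0, timepoint_label = NULL) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  data <- array(as.numeric(img), dim(img)[1:3])
  volume_image(data, spacing, slice_axis = slice_axis,
               slice_thickness_mm = slice_thickness_mm %||% spacing[slice_axis],
               slice_gap_mm = slice_gap_mm, timepoint_label = timepoint_label)
}

#' Brain mask with hemisphere bookkeeping
#'
#' @param mask logical 3D array.
#' @param midline_plane sagittal index of the interhemispheric plane; voxels
#'   with sagittal index greater than the plane are on the "right" side.
#' @param affected_side `"left"` or `"right"` (side of the occlusion; right
#'   in the middle cerebral artery occlusion model emulated here).
#' @return object of class `brain_mask`.
#' @export
brain_mask <- function(mask, midline_plane, affected_side = "right") {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("brain_mask: mask is empty")
  midline_plane <- as.integer(midline_plane)
  if (midline_plane < 1L || midline_plane > dim(mask)[1]) {
    stop("brain_mask: midline_plane outside grid")
  }
  affected_side <- match.arg(affected_side, c("left", "right"))
  structure(list(mask = mask, midline_plane = midline_plane,
                 affected_side = affected_side),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d voxels, midline at sagittal index %d, affected side: %s\n",
              sum(x$mask), x$midline_plane, x$affected_side))
  invisible(x)
}

#' Dice overlap of two masks
#' @param a,b logical arrays of identical dimension.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
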