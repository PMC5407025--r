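#' Threshold-based lesion segmentation on T2
#'
#' Automated surrogate for manual hyperintense-lesion tracing: voxels of the
#' affected hemisphere brighter than `mean + k_sd * SD` of the contralateral
#' hemisphere, reduced to the largest 26-connected component with interior
#' holes filled. An externally drawn lesion mask can be used anywhere a
#' lesion mask is accepted, bypassing this rule.
#'
#' @param t2 normalized T2-weighted [volume_image()].
#' @param mask a [brain_mask()].
#' @param k_sd threshold multiplier (default 2).
#' @param min_lesion_mm3 smallest plausible lesion: a mean + 2 SD threshold
#'   always passes a few percent of pure noise, so a largest component below
#'   this volume is reported as "no lesion".
#' @return logical lesion array (empty, with a warning, when nothing
#'   lesion-sized exceeds the threshold - valid for controls and late
#'   timepoints).
#' @export
segment_lesion <- function(t2, mask, k_sd = 2, min_lesion_mm3 = 1) {
  stopifnot(inherits(t2, "volume_image"), inherits(mask, "brain_mask"))
  hemi <- split_hemispheres(mask)
  con <- roi_moments(t2, hemi$contralateral)
  thr <- con$mean + k_sd * con$sd
  cand <- hemi$affected & (t2$data > thr)
  if (any(cand)) cand <- largest_component(cand, connectivity = 26L)
  if (sum(cand) * voxel_volume_mm3(t2) < min_lesion_mm3) {
    warning("segment_lesion: no lesion-sized hyperintense component; empty lesion mask")
    return(cand & FALSE)
  }
  fill_holes3(cand)
}

#' Per-slice cross-sectional areas of a mask
#'
#' @param lesion logical array on the volume's grid.
#' @param vol the [volume_image()] supplying the grid geometry.
#' @return data frame with `slice_index` and `area_mm2` (voxel count times
#'   in-plane voxel area) for every through-plane slice.
#' @export
slice_areas <- function(lesion, vol) {
  stopifnot(inherits(vol, "volume_image"))
  if (!identical(dim(lesion), dim(vol$data))) {
    stop("slice_areas: mask grid does not match the volume grid")
  }
  counts <- apply(lesion, vol$slice_axis, sum)
  data.frame(slice_index = seq_along(counts),
             area_mm2 = counts * in_plane_area_mm2(vol))
}

#' Volume from slice areas with interslice-gap interpolation
#'
#' Each slice contributes `area * thickness`; each gap between neighbouring
#' slices contributes `gap * (area_i + area_{i+1}) / 2` (the mean area of
#' the two neighbour slices); the total volume is the sum of all slice and
#' gap contributions.
#'
#' @param areas numeric vector of per-slice areas (mm^2, in slice order).
#' @param thickness_mm acquired slice thickness (> 0).
#' @param gap_mm interslice gap (>= 0).
#' @return volume in mm^3.
#' @export
interpolated_volume <- function(areas, thickness_mm, gap_mm) {
  areas <- as.numeric(areas)
  if (length(areas) < 1L) stop("interpolated_volume: need at least one area")
  if (any(areas < 0)) stop("interpolated_volume: negative area")
  if (thickness_mm <= 0) stop("interpolated_volume: thickness must be > 0")
  if (gap_mm < 0) stop("interpolated_volume: gap must be >= 0")
  v <- sum(areas) * thickness_mm
  if (length(areas) > 1L && gap_mm > 0) {
    k <- length(areas)
    v <- v + gap_mm * sum((areas[-1] + areas[-k]) / 2)
  }
  v
}

#' Lesion volume as a percentage of brain volume
#'
#' @param lesion_vol,brain_vol volumes in mm^3; the brain volume is expected
#'   to come from the same slice-plus-gap procedure applied to the
#'   brain-mask slice areas.
#' @return percentage (100 * lesion / brain).
#' @export
infarct_percent <- function(lesion_vol, brain_vol) {
  if (brain_vol <= 0) stop("infarct_percent: brain volume must be > 0")
  100 * lesion_vol / brain_vol
}

#' Residual infarct at the late timepoint
#'
#' @param vol_48h baseline (48 h) lesion volume in mm^3 (> 0).
#' @param vol_9d late (9 d) lesion volume in mm^3.
#' @return object of class `residual_infarct` with `percent_of_48h`.
#' @export
residual_percent <- function(vol_48h, vol_9d) {
  if (vol_48h <= 0) stop("residual_percent: undefined baseline (48 h volume is 0)")
  structure(list(percent_of_48h = 100 * vol_9d / vol_48h),
            class = "residual_infarct")
}

#' Full infarct volumetry for one volume
#'
#' Segments the lesion, measures per-slice areas of lesion and brain,
#' integrates both with the slice-plus-gap rule and reports the lesion
#' volume as a brain-volume percentage.
#'
#' @param t2 normalized T2-weighted [volume_image()].
#' @param mask a [brain_mask()].
#' @param k_sd segmentation threshold multiplier.
#' @param lesion_mask optional externally provided lesion mask (skips the
#'   automatic segmentation).
#' @return object of class `infarct_volume_result`: `per_slice_area_mm2`,
#'   `lesion_volume_mm3`, `brain_volume_mm3`, `infarct_percent`,
#'   `timepoint_label`.
#' @export
infarct_volumetry <- function(t2, mask, k_sd = 2, lesion_mask = NULL) {
  lesion <- lesion_mask %||% segment_lesion(t2, mask, k_sd)
  la <- slice_areas(lesion, t2)
  ba <- slice_areas(mask$mask, t2)
  lv <- interpolated_volume(la$area_mm2, t2$slice_thickness_mm, t2$slice_gap_mm)
  bv <- interpolated_volume(ba$area_mm2, t2$slice_thickness_mm, t2$slice_gap_mm)
  structure(list(per_slice_area_mm2 = la,
                 lesion_volume_mm3 = lv, brain_volume_mm3 = bv,
                 infarct_percent = infarct_percent(lv, bv),
                 timepoint_label = t2$timepoint_label,
                 lesion_mask = lesion),
            class = "infarct_volume_result")
}

#' @export
print.infarct_volume_result <- function(x, ...) {
  cat(sprintf("<infarct_volume_result> lesion %.2f mm^3 / brain %.2f mm^3 = %.2f%%\n",
              x$lesion_volume_mm3, x$brain_volume_mm3, x$infarct_percent))
  invisible(x)
}
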