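#' Split a brain mask into affected and contralateral hemispheres
#'
#' The split runs along the sagittal plane at `midline_plane`; voxels exactly
#' on the plane are assigned to the contralateral side (a conservative
#' tie-break that never inflates the affected ROI). The two hemisphere masks
#' are disjoint and their union is the brain mask.
#'
#' @param mask a [brain_mask()].
#' @return list with logical arrays `affected` and `contralateral`.
#' @export
split_hemispheres <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  sag <- slice.index(mask$mask, 1)
  mid <- mask$midline_plane
  if (mask$affected_side == "right") {
    affected <- mask$mask & sag > mid
    contralateral <- mask$mask & sag <= mid
  } else {
    affected <- mask$mask & sag < mid
    contralateral <- mask$mask & sag >= mid
  }
  if (!any(affected) || !any(contralateral)) {
    stop("split_hemispheres: empty hemisphere")
  }
  list(affected = affected, contralateral = contralateral)
}

#' Mean and standard deviation within a region of interest
#'
#' @param vol a [volume_image()].
#' @param roi logical array (>= 2 voxels).
#' @return object of class `roi_stats`: `mean`, `sd` (sample SD, divisor
#'   n - 1) and `n_voxels`.
#' @export
roi_moments <- function(vol, roi) {
  stopifnot(inherits(vol, "volume_image"), identical(dim(roi), dim(vol$data)))
  n <- sum(roi)
  if (n < 2L) stop("roi_moments: ROI must contain at least 2 voxels")
  x <- vol$data[roi]
  structure(list(mean = mean(x), sd = sd(x), n_voxels = n), class = "roi_stats")
}

#' Per-slice cell-signal-intensity asymmetry (delta-CSI)
#'
#' The root-sum-of-squares of the two hemispheres' coefficients of
#' variation:
#' `sqrt((sd_contra/mean_contra)^2 + (sd_aff/mean_aff)^2)`.
#' Nonnegative, zero only when both ROIs are constant, and invariant under
#' any positive rescaling of the intensities.
#'
#' @param aff,contra [roi_moments()] of the affected and contralateral
#'   hemisphere ROI on one slice.
#' @return delta-CSI value (>= 0).
#' @export
slice_delta_csi <- function(aff, contra) {
  stopifnot(inherits(aff, "roi_stats"), inherits(contra, "roi_stats"))
  if (aff$mean <= 0 || contra$mean <= 0) {
    stop("slice_delta_csi: nonpositive ROI mean (normalization failed?)")
  }
  sqrt((contra$sd / contra$mean)^2 + (aff$sd / aff$mean)^2)
}

# default analysis slices: n slices centred on the through-plane centroid
# of `focus` (the lesion if available, otherwise the brain)
select_dcsi_slices <- function(focus, slice_axis, n_slices = 7L) {
  d <- dim(focus)[slice_axis]
  centroid <- sum(slice.index(focus, slice_axis) * focus) / sum(focus)
  c0 <- as.integer(round(centroid))
  half <- (n_slices - 1L) %/% 2L
  lo <- max(1L, min(c0 - half, d - n_slices + 1L))
  seq(lo, min(d, lo + n_slices - 1L))
}

#' Per-animal delta-CSI over a set of slices
#'
#' Computes the hemisphere asymmetry statistic slice by slice on the
#' T2*-weighted volume and averages it over the analysed slices (seven
#' centrally located lesion-spanning slices by default).
#'
#' @param t2star a [volume_image()].
#' @param mask a [brain_mask()].
#' @param slice_indices slices to analyse; default: 7 slices centred on the
#'   through-plane centroid of `lesion_mask` (or of the brain if no lesion
#'   mask is given).
#' @param lesion_mask optional logical array used only for slice selection.
#' @param n_slices number of slices when `slice_indices` is `NULL`.
#' @return object of class `delta_csi_result`: `per_slice` data frame,
#'   `mean_dcsi`, `sd_dcsi`, `n_slices`.
#' @export
animal_delta_csi <- function(t2star, mask, slice_indices = NULL,
                             lesion_mask = NULL, n_slices = 7L) {
  stopifnot(inherits(t2star, "volume_image"), inherits(mask, "brain_mask"))
  hemi <- split_hemispheres(mask)
  ax <- t2star$slice_axis
  if (is.null(slice_indices)) {
    focus <- if (!is.null(lesion_mask) && any(lesion_mask)) lesion_mask else mask$mask
    slice_indices <- select_dcsi_slices(focus, ax, n_slices)
  }
  sl_idx <- slice.index(t2star$data, ax)
  rows <- list()
  for (s in slice_indices) {
    on_slice <- sl_idx == s
    aff_roi <- hemi$affected & on_slice
    con_roi <- hemi$contralateral & on_slice
    if (sum(aff_roi) < 2L || sum(con_roi) < 2L) {
      warning(sprintf("animal_delta_csi: slice %d skipped (empty hemisphere)", s))
      next
    }
    aff <- roi_moments(t2star, aff_roi)
    con <- roi_moments(t2star, con_roi)
    rows[[length(rows) + 1L]] <- data.frame(
      slice_index = s, dcsi = slice_delta_csi(aff, con),
      aff_mean = aff$mean, aff_sd = aff$sd,
      contra_mean = con$mean, contra_sd = con$sd
    )
  }
  if (length(rows) == 0L) stop("animal_delta_csi: all slices skipped")
  per_slice <- do.call(rbind, rows)
  structure(list(per_slice = per_slice,
                 mean_dcsi = mean(per_slice$dcsi),
                 sd_dcsi = sd(per_slice$dcsi),
                 n_slices = nrow(per_slice)),
            class = "delta_csi_result")
}

#' @export
print.delta_csi_result <- function(x, ...) {
  cat(sprintf("<delta_csi_result> mean dCSI %.5f (SD %.5f) over %d slices\n",
              x$mean_dcsi, x$sd_dcsi, x$n_slices))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact two-sided p-value by full enumeration of the group-label
#' assignments (with midranks for ties) when the combined sample size is at
#' most `exact_max_n`; tie-corrected normal approximation with continuity
#' correction otherwise. The reported U is the statistic of `group_a`.
#'
#' @param group_a,group_b numeric vectors (nonempty).
#' @param exact_max_n largest combined n for the exact branch.
#' @return list with `U` and `p_two_sided`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max_n = 12L) {
  na <- length(group_a)
  nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("mann_whitney_u: empty group")
  x <- c(group_a, group_b)
  r <- rank(x)  # midranks
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  n <- na + nb
  if (n <= exact_max_n) {
    # permutation distribution of U over all label assignments
    sets <- combn(n, na)
    Rsum <- colSums(matrix(r[sets], nrow = na))
    U_all <- Rsum - na * (na + 1) / 2
    p <- mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
  } else {
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U_obs - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-max(z, 0))
    }
  }
  list(U = U_obs, p_two_sided = min(p, 1))
}
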