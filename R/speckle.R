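#' Median-filter residual enhancement
#'
#' Subtracts the median-filtered (de-noised) volume from the original and
#' takes the absolute value voxelwise: smooth structure cancels, few-voxel
#' deviations of either sign survive. Edges are handled by reflection.
#'
#' @param vol a [volume_image()].
#' @param kernel_vox cubic kernel side (odd, >= 3).
#' @return residual [volume_image()] (>= 0 everywhere).
#' @export
median_residual <- function(vol, kernel_vox = 3L) {
  stopifnot(inherits(vol, "volume_image"))
  kernel_vox <- as.integer(kernel_vox)
  if (kernel_vox %% 2L == 0L || kernel_vox < 3L) {
    stop("median_residual: kernel must be odd and >= 3")
  }
  d <- dim(vol$data)
  med <- array(median_filter3_cpp(as.vector(vol$data), d, kernel_vox), d)
  with_data(vol, abs(vol$data - med))
}

#' Local adaptive (Wiener) denoising
#'
#' Classical local-statistics Wiener filter: with local mean `mu` and local
#' variance `s2` over a cubic window and `nu` the volume-mean of `s2`,
#' `out = mu + max(s2 - nu, 0) / max(s2, nu) * (x - mu)`. Flat regions are
#' pulled to their local mean, high-variance detail passes through.
#'
#' @param vol a [volume_image()] (typically the median residual).
#' @param window_vox cubic window side (odd).
#' @return filtered [volume_image()].
#' @export
wiener_denoise <- function(vol, window_vox = 3L) {
  stopifnot(inherits(vol, "volume_image"))
  window_vox <- as.integer(window_vox)
  if (window_vox %% 2L == 0L) stop("wiener_denoise: window must be odd")
  x <- vol$data
  mu <- box_mean3(x, window_vox)
  s2 <- pmax(box_mean3(x^2, window_vox) - mu^2, 0)
  nu <- mean(s2)
  if (nu <= 0) return(with_data(vol, mu))
  out <- mu + pmax(s2 - nu, 0) / pmax(s2, nu) * (x - mu)
  with_data(vol, out)
}

#' Mean + 2 SD speckle thresholding
#'
#' Voxels of the reference hemisphere whose filtered residual intensity is
#' strictly higher than the hemisphere mean plus `k_sd` sample standard
#' deviations are flagged as speckled.
#'
#' @param filtered [volume_image()] of filtered residuals.
#' @param hemisphere logical array (>= 2 voxels) supplying both the
#'   threshold statistics and the candidate voxels.
#' @param k_sd threshold multiplier (default 2).
#' @return list with `mask` (logical array, subset of `hemisphere`) and
#'   `threshold`.
#' @export
threshold_speckles <- function(filtered, hemisphere, k_sd = 2) {
  stopifnot(inherits(filtered, "volume_image"),
            identical(dim(hemisphere), dim(filtered$data)))
  if (sum(hemisphere) < 2L) stop("threshold_speckles: hemisphere must have >= 2 voxels")
  x <- filtered$data[hemisphere]
  thr <- mean(x) + k_sd * sd(x)
  list(mask = hemisphere & (filtered$data > thr), threshold = thr)
}

#' Histogram-based hypointense selection
#'
#' The speckled voxels contain both hyper- and hypointense signal; only the
#' hypointense class is cell-derived. The speckled voxels' original
#' intensities are split at the two-class (Otsu) threshold and the low class
#' is kept, always restricted to intensities below the brain mean. When the
#' intensity set is effectively unimodal (Otsu separation strength eta^2
#' below `eta_bimodal`), the split is meaningless and the whole set is
#' classified at once: kept if its mean lies below `hypo_margin` times the
#' brain mean (clearly hypointense), discarded otherwise (guards the
#' all-hyperintense and the pure-noise case).
#'
#' @param speckled logical array of speckled voxels.
#' @param original the normalized [volume_image()] the mask was derived from.
#' @param brain_mean mean brain intensity of `original` (about 1000 after
#'   normalization).
#' @param eta_bimodal minimal Otsu between-class variance fraction to accept
#'   the two-class split.
#' @param hypo_margin unimodal sets are kept only if their mean is below
#'   this fraction of `brain_mean`.
#' @return logical array of hypointense (cell-derived) voxels.
#' @export
classify_hypointense <- function(speckled, original, brain_mean,
                                 eta_bimodal = 0.8, hypo_margin = 0.95) {
  stopifnot(inherits(original, "volume_image"),
            identical(dim(speckled), dim(original$data)))
  out <- speckled & FALSE
  if (!any(speckled)) return(out)
  vals <- original$data[speckled]
  ot <- otsu_threshold(vals)
  if (ot$eta_sq >= eta_bimodal) {
    keep <- vals < ot$threshold & vals < brain_mean
  } else if (mean(vals) < hypo_margin * brain_mean) {
    keep <- vals < brain_mean
  } else {
    keep <- rep(FALSE, length(vals))
  }
  out[speckled] <- keep
  out
}

#' Parameters of the T2* speckle re-analysis
#'
#' @param median_kernel_vox median filter kernel (odd).
#' @param wiener_window_vox Wiener filter window (odd).
#' @param k_sd threshold multiplier for [threshold_speckles()].
#' @param reference hemisphere supplying the threshold statistics:
#'   `"affected"` (the literal reading for a right-sided occlusion with the
#'   right hemisphere affected) or `"contralateral"`.
#' @param erode_mask_vox iterations of 6-connected erosion applied to the
#'   hemisphere mask before thresholding; brain-edge voxels neighbouring
#'   background carry large partial-volume residuals that are not cells.
#' @param eta_bimodal,hypo_margin see [classify_hypointense()].
#' @param connectivity cluster connectivity (6 or 26).
#' @param match_tol_vox centroid distance tolerance for longitudinal cluster
#'   matching (voxels).
#' @return list of class `speckle_config`.
#' @export
speckle_config <- function(median_kernel_vox = 3L, wiener_window_vox = 3L,
                           k_sd = 2, reference = c("affected", "contralateral"),
                           erode_mask_vox = 1L, eta_bimodal = 0.8,
                           hypo_margin = 0.95, connectivity = 26L,
                           match_tol_vox = 3) {
  structure(list(median_kernel_vox = as.integer(median_kernel_vox),
                 wiener_window_vox = as.integer(wiener_window_vox),
                 k_sd = k_sd, reference = match.arg(reference),
                 erode_mask_vox = as.integer(erode_mask_vox),
                 eta_bimodal = eta_bimodal, hypo_margin = hypo_margin,
                 connectivity = as.integer(connectivity),
                 match_tol_vox = match_tol_vox),
            class = "speckle_config")
}

# connected clusters of a logical mask: voxel lists and centroids
mask_clusters <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  vox <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  lapply(seq_len(n), function(i) {
    v <- vox[labs == i, , drop = FALSE]
    list(voxels = v, centroid = colMeans(v), size = nrow(v))
  })
}

#' T2* speckle re-analysis of one volume
#'
#' Runs the full chain on a preprocessed (bias-corrected, normalized,
#' aligned) T2*-weighted volume: median-filter residual, local Wiener
#' denoising, mean + 2 SD thresholding within the (eroded) affected
#' hemisphere, and histogram-based hypointense selection; then counts the
#' resulting voxels and their connected clusters.
#'
#' @param t2star preprocessed T2*-weighted [volume_image()].
#' @param mask a [brain_mask()].
#' @param config a [speckle_config()].
#' @return object of class `speckle_map`: `speckled_mask`, `hypo_mask`,
#'   `voxel_count`, `clusters`, `threshold_value`, `timepoint_label`.
#' @export
build_speckle_map <- function(t2star, mask, config = speckle_config()) {
  stopifnot(inherits(t2star, "volume_image"), inherits(mask, "brain_mask"),
            inherits(config, "speckle_config"))
  hemi <- split_hemispheres(mask)
  erode_n <- config$erode_mask_vox
  cand <- hemi$affected
  ref <- if (config$reference == "affected") hemi$affected else hemi$contralateral
  if (erode_n > 0L) {
    cand <- erode3(cand, connectivity = 6L, iterations = erode_n)
    ref <- erode3(ref, connectivity = 6L, iterations = erode_n)
  }
  res <- median_residual(t2star, config$median_kernel_vox)
  wien <- wiener_denoise(res, config$wiener_window_vox)
  x <- wien$data[ref]
  thr <- mean(x) + config$k_sd * sd(x)
  speckled <- cand & (wien$data > thr)
  brain_mean <- mean(t2star$data[mask$mask])
  hypo <- classify_hypointense(speckled, t2star, brain_mean,
                               eta_bimodal = config$eta_bimodal,
                               hypo_margin = config$hypo_margin)
  structure(list(speckled_mask = speckled, hypo_mask = hypo,
                 voxel_count = sum(hypo),
                 clusters = mask_clusters(hypo, config$connectivity),
                 threshold_value = thr,
                 timepoint_label = t2star$timepoint_label),
            class = "speckle_map")
}

#' @export
print.speckle_map <- function(x, ...) {
  cat(sprintf("<speckle_map> %d hypointense voxels in %d clusters (threshold %.3f)%s\n",
              x$voxel_count, length(x$clusters), x$threshold_value,
              if (is.null(x$timepoint_label)) "" else
                paste0(", timepoint ", x$timepoint_label)))
  invisible(x)
}

#' Longitudinal comparison of two speckle maps
#'
#' Both maps must live in the same (registered) frame; `transform` is the
#' rigid transform that brought the later volume there and is carried into
#' the report. Counts are compared and clusters matched greedily by nearest
#' centroid within `match_tol_vox`; unmatched late clusters are "appeared",
#' unmatched early clusters "disappeared" - the signature of cell migration.
#'
#' @param map_48h,map_9d [build_speckle_map()] results on a common grid.
#' @param transform optional [rigid_transform()] used for the alignment.
#' @param match_tol_vox centroid matching tolerance (voxels).
#' @return object of class `migration_report`: counts at both timepoints,
#'   `change_pct`, matched cluster pairs, `appeared`, `disappeared`.
#' @export
compare_timepoints <- function(map_48h, map_9d, transform = NULL,
                               match_tol_vox = 3) {
  stopifnot(inherits(map_48h, "speckle_map"), inherits(map_9d, "speckle_map"))
  if (!identical(dim(map_48h$hypo_mask), dim(map_9d$hypo_mask))) {
    stop("compare_timepoints: speckle maps on different grids (register first)")
  }
  c48 <- map_48h$voxel_count
  c9 <- map_9d$voxel_count
  change <- if (c48 > 0) 100 * (c9 - c48) / c48 else NA_real_
  cent48 <- do.call(rbind, lapply(map_48h$clusters, `[[`, "centroid"))
  cent9 <- do.call(rbind, lapply(map_9d$clusters, `[[`, "centroid"))
  n48 <- length(map_48h$clusters)
  n9 <- length(map_9d$clusters)
  matched <- data.frame(idx_48h = integer(0), idx_9d = integer(0),
                        dist_vox = numeric(0))
  if (n48 > 0L && n9 > 0L) {
    dmat <- sqrt(pmax(outer(rowSums(cent48^2), rowSums(cent9^2), `+`) -
                        2 * cent48 %*% t(cent9), 0))
    pairs <- which(dmat <= match_tol_vox, arr.ind = TRUE)
    if (nrow(pairs) > 0L) {
      ord <- order(dmat[pairs])
      used48 <- logical(n48)
      used9 <- logical(n9)
      for (k in ord) {
        i <- pairs[k, 1]
        j <- pairs[k, 2]
        if (used48[i] || used9[j]) next
        used48[i] <- TRUE
        used9[j] <- TRUE
        matched <- rbind(matched, data.frame(idx_48h = i, idx_9d = j,
                                             dist_vox = dmat[i, j]))
      }
    }
  }
  appeared <- setdiff(seq_len(n9), matched$idx_9d)
  disappeared <- setdiff(seq_len(n48), matched$idx_48h)
  structure(list(count_48h = c48, count_9d = c9, change_pct = change,
                 matched = matched,
                 appeared = appeared, disappeared = disappeared,
                 n_appeared = length(appeared),
                 n_disappeared = length(disappeared),
                 transform = transform),
            class = "migration_report")
}

#' @export
print.migration_report <- function(x, ...) {
  cat(sprintf("<migration_report> %d -> %d voxels (%+.1f%%); %d matched, %d appeared, %d disappeared clusters\n",
              x$count_48h, x$count_9d, x$change_pct, nrow(x$matched),
              x$n_appeared, x$n_disappeared))
  invisible(x)
}
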