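#' Polynomial bias-field correction
#'
#' Fits a smooth multiplicative intensity field to the log-intensities inside
#' the brain mask by least-squares over a 3D polynomial basis, and divides it
#' out. The fit is made robust to anatomical structure (the hyperintense
#' lesion is intensity, not coil inhomogeneity) by iteratively refitting with
#' voxels excluded whose log-residual exceeds `trim_k` median absolute
#' deviations. The estimated field is rescaled so that the mean intensity
#' over the mask is preserved exactly; voxels outside the mask are returned
#' unchanged.
#'
#' @param vol a [volume_image()].
#' @param mask a [brain_mask()].
#' @param poly_order polynomial order of the fitted field (1-4; default 3).
#' @param trim_iter robust refit iterations (0 = plain least squares).
#' @param trim_k residual cutoff in scaled MADs.
#' @return list with `vol` (corrected volume) and `estimated_field` (a
#'   [volume_image()]; meaningful inside the mask).
#' @export
correct_bias <- function(vol, mask, poly_order = 3L, trim_iter = 2L,
                         trim_k = 2.5) {
  stopifnot(inherits(vol, "volume_image"), inherits(mask, "brain_mask"))
  poly_order <- as.integer(poly_order)
  if (poly_order < 1L || poly_order > 4L) {
    stop("correct_bias: poly_order must be in 1..4")
  }
  d <- dim(vol$data)
  vox <- which(mask$mask, arr.ind = TRUE)
  X <- poly_basis3(d, poly_order, vox)
  if (nrow(X) < 10L * ncol(X)) {
    stop("correct_bias: mask too small for the requested polynomial order")
  }
  y <- vol$data[mask$mask]
  floor_val <- 1e-6 * max(mean(y), .Machine$double.eps)
  ly <- log(pmax(y, floor_val))
  fit <- stats::lm.fit(X, ly)
  for (it in seq_len(trim_iter)) {
    r <- ly - X %*% fit$coefficients
    s <- stats::mad(r)
    if (s <= 0) break
    keep <- abs(r) <= trim_k * s
    if (sum(keep) < 10L * ncol(X)) break
    fit <- stats::lm.fit(X[keep, , drop = FALSE], ly[keep])
  }
  X_full <- poly_basis3(d, poly_order)
  field <- array(exp(X_full %*% fit$coefficients), d)
  field <- field / mean(field[mask$mask])
  # rescale so the mask mean is preserved exactly after division
  s <- mean(y / field[mask$mask]) / mean(y)
  field <- field * s
  out <- vol$data
  out[mask$mask] <- y / field[mask$mask]
  list(vol = with_data(vol, out), estimated_field = with_data(vol, field))
}

#' Automatic brain extraction
#'
#' Thresholds the volume at the two-class (Otsu) histogram threshold, keeps
#' the largest 26-connected component, applies a morphological closing and
#' fills interior holes. The interhemispheric midline is placed at the
#' sagittal index of the mask centroid.
#'
#' @param vol a [volume_image()] with background substantially darker than
#'   tissue.
#' @param affected_side hemisphere label carried by the returned mask.
#' @return a [brain_mask()].
#' @export
extract_brain <- function(vol, affected_side = "right") {
  stopifnot(inherits(vol, "volume_image"))
  ot <- otsu_threshold(as.vector(vol$data))
  m <- vol$data > ot$threshold
  if (!any(m)) stop("extract_brain: no above-threshold voxels (empty segmentation)")
  m <- largest_component(m, connectivity = 26L)
  m <- fill_holes3(close3(m))
  centroid <- sum(slice.index(m, 1) * m) / sum(m)
  brain_mask(m, midline_plane = as.integer(round(centroid)),
             affected_side = affected_side)
}

#' Normalize the mean intensity over the brain to a target value
#'
#' Scales the whole volume so that the mean intensity over the brain mask
#' equals `target` (1000 by convention). Exactly scale-invariant and
#' idempotent.
#'
#' @param vol a [volume_image()].
#' @param mask a [brain_mask()]; set `region = "grid"` to normalize by the
#'   whole-grid mean instead of the brain-mask mean.
#' @param target target mean intensity.
#' @param region `"mask"` (default) or `"grid"`.
#' @return normalized [volume_image()].
#' @export
normalize_mean <- function(vol, mask, target = 1000, region = c("mask", "grid")) {
  stopifnot(inherits(vol, "volume_image"))
  region <- match.arg(region)
  m <- if (region == "mask") mean(vol$data[mask$mask]) else mean(vol$data)
  if (!is.finite(m) || m <= 0) {
    stop("normalize_mean: nonpositive mean over the normalization region")
  }
  with_data(vol, vol$data * (target / m))
}

# normalized cross-correlation of a fixed vector with a transformed volume
ncc_objective <- function(params, mov_vec, dimv, spacing, center0, fix_vec) {
  R <- rotation_matrix(params[1:3])
  res <- resample_rigid_cpp(mov_vec, dimv, R, params[4:6], spacing, center0, 0)
  v <- suppressWarnings(cor(fix_vec, res))
  if (is.na(v)) -1 else v
}

#' Rigid inter-session registration
#'
#' Finds the 6 degree-of-freedom rigid transform maximizing the normalized
#' cross-correlation between the transformed moving volume and the fixed
#' volume. The integer-voxel translation is located first by the peak of the
#' FFT cross-correlation, then all 6 parameters are refined by Nelder-Mead
#' at a 2x in-plane subsampled level and polished at full resolution.
#' Intended for longitudinal same-animal alignment (small rotations and
#' translations).
#'
#' @param moving,fixed [volume_image()]s on the same grid.
#' @param refine_maxit iteration cap of the full-resolution polish.
#' @return list with `transform` (a [rigid_transform()], translation in
#'   voxels of the moving grid) and `resampled` (moving volume resampled into
#'   the fixed frame). If the search cannot improve on the identity the
#'   identity is returned (with a warning when strictly worse).
#' @export
register_rigid <- function(moving, fixed, refine_maxit = 200L) {
  stopifnot(inherits(moving, "volume_image"), inherits(fixed, "volume_image"))
  d <- dim(moving$data)
  if (!identical(d, dim(fixed$data))) stop("register_rigid: grid mismatch")
  sp <- moving$voxel_size_mm
  center0 <- (d - 1) / 2

  # integer-voxel translation start: peak of the circular cross-correlation
  cc <- Re(stats::fft(stats::fft(fixed$data) * Conj(stats::fft(moving$data)),
                      inverse = TRUE))
  k <- arrayInd(which.max(cc), d) - 1L
  shift <- ifelse(k > d / 2, k - d, k)
  start <- c(0, 0, 0, as.numeric(shift) * sp)

  # coarse level: stride-2 subsampling in-plane
  i1 <- seq(1L, d[1], by = 2L)
  i2 <- seq(1L, d[2], by = 2L)
  dc <- c(length(i1), length(i2), d[3])
  spc <- sp * c(2, 2, 1)
  cc0 <- (dc - 1) / 2
  mov_c_vec <- as.vector(moving$data[i1, i2, , drop = FALSE])
  fix_c_vec <- as.vector(fixed$data[i1, i2, , drop = FALSE])
  obj_c <- function(p) -ncc_objective(p, mov_c_vec, dc, spc, cc0, fix_c_vec)
  fit_c <- optim(start, obj_c, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-9,
                                parscale = c(1, 1, 1, 0.2, 0.2, 0.5)))

  # full-resolution polish
  mov_vec <- as.vector(moving$data)
  fix_vec <- as.vector(fixed$data)
  obj_f <- function(p) -ncc_objective(p, mov_vec, d, sp, center0, fix_vec)
  fit <- optim(fit_c$par, obj_f, method = "Nelder-Mead",
               control = list(maxit = refine_maxit, reltol = 1e-10,
                              parscale = c(0.5, 0.5, 0.5, 0.1, 0.1, 0.2)))
  identity_val <- obj_f(rep(0, 6))
  if (fit$value >= identity_val) {
    if (fit$value > identity_val + 1e-9) {
      warning("register_rigid: search did not improve on the identity; returning identity")
    }
    tr <- rigid_transform()
    return(list(transform = tr, resampled = moving))
  }
  tr <- rigid_transform(rotation_deg = fit$par[1:3],
                        translation_vox = fit$par[4:6] / sp)
  list(transform = tr, resampled = apply_rigid(moving, tr))
}
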