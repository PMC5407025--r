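#' Rigid (6 degree-of-freedom) transform
#'
#' Rotation is specified as extrinsic angles about the x, y and z axes
#' (applied in that order, `R = Rz Ry Rx`) in degrees; translation in voxels
#' of the grid it is applied to. The rotation acts about the grid centre in
#' physical (mm) coordinates unless another centre is given.
#'
#' @param rotation_deg three rotation angles (degrees).
#' @param translation_vox three translations (voxels).
#' @param center optional rotation centre (1-based voxel coordinates).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_vox = c(0, 0, 0), center = NULL) {
  rotation_deg <- as.numeric(rotation_deg)
  translation_vox <- as.numeric(translation_vox)
  stopifnot(length(rotation_deg) == 3L, length(translation_vox) == 3L,
            all(is.finite(rotation_deg)), all(is.finite(translation_vox)))
  structure(list(rotation_deg = rotation_deg,
                 translation_vox = translation_vox, center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %.3f %.3f %.3f | trans (vox): %.3f %.3f %.3f\n",
              x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3],
              x$translation_vox[1], x$translation_vox[2], x$translation_vox[3]))
  invisible(x)
}

is_identity_transform <- function(tr, tol = 0) {
  all(abs(tr$rotation_deg) <= tol) && all(abs(tr$translation_vox) <= tol)
}

rotation_matrix <- function(rotation_deg) {
  th <- rotation_deg * pi / 180
  ca <- cos(th[1]); sa <- sin(th[1])
  cb <- cos(th[2]); sb <- sin(th[2])
  cc <- cos(th[3]); sc <- sin(th[3])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Euler angles (degrees) of R = Rz Ry Rx
rotation_angles <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c) * 180 / pi
}

#' Invert a rigid transform
#' @param tr a [rigid_transform()].
#' @param voxel_size_mm voxel spacing of the grid the transform lives on
#'   (needed because translations are stored in voxels but rotation acts in mm).
#' @return the inverse [rigid_transform()].
#' @export
invert_rigid <- function(tr, voxel_size_mm) {
  R <- rotation_matrix(tr$rotation_deg)
  t_mm <- tr$translation_vox * voxel_size_mm
  t_inv <- as.numeric(-crossprod(R, t_mm))  # -R^T t
  rigid_transform(rotation_angles(t(R)), t_inv / voxel_size_mm, tr$center)
}

#' Resample a volume under a rigid transform
#'
#' Trilinear interpolation about the volume centre; voxels mapped from
#' outside the grid take the `fill` value. The identity transform returns
#' the input bit-exact.
#'
#' @param vol a [volume_image()].
#' @param transform a [rigid_transform()]; rotations must be below 30 degrees
#'   and translations below a quarter of the grid extent.
#' @param fill background fill value.
#' @return transformed [volume_image()].
#' @export
apply_rigid <- function(vol, transform, fill = 0) {
  stopifnot(inherits(vol, "volume_image"), inherits(transform, "rigid_transform"))
  d <- dim(vol$data)
  if (any(abs(transform$rotation_deg) >= 30)) {
    stop("apply_rigid: rotation magnitude must be < 30 degrees")
  }
  if (any(abs(transform$translation_vox) >= d / 4)) {
    stop("apply_rigid: translation must be < 1/4 of the grid extent")
  }
  if (is_identity_transform(transform)) return(vol)
  center <- (transform$center %||% ((d + 1) / 2)) - 1  # 0-based for the kernel
  R <- rotation_matrix(transform$rotation_deg)
  t_mm <- transform$translation_vox * vol$voxel_size_mm
  out <- resample_rigid_cpp(as.vector(vol$data), d, R, t_mm,
                            vol$voxel_size_mm, center, fill)
  with_data(vol, array(out, d))
}
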