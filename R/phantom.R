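#' Configuration of the synthetic brain phantom
#'
#' Builds the parameter set for [generate_phantom()]. The default geometry
#' emulates a coronal rodent-brain acquisition: 14 x 11 mm in-plane field of
#' view on a 128 x 104 grid and 20 slices of 0.8 mm thickness separated by a
#' 0.2 mm gap (1 mm centre-to-centre). The brain is an ellipsoid split into
#' two hemispheres by the mid-sagittal plane; an ellipsoidal ischaemic lesion
#' sits in the affected (right) hemisphere and appears hyperintense on the
#' T2-weighted volume; iron-labelled cell deposits are planted as few-voxel
#' hypointense speckles in and around the lesion on the T2*-weighted volume.
#'
#' Intensities are phenomenological (no MR physics): homogeneous tissue at
#' `tissue_intensity`, background 0, multiplicative smooth bias field, then
#' additive noise.
#'
#' @param grid_shape voxels per axis.
#' @param voxel_size_mm centre-to-centre spacing per axis (mm); the third
#'   axis is the through-plane axis and must equal
#'   `slice_thickness_mm + slice_gap_mm`.
#' @param slice_thickness_mm,slice_gap_mm acquired slice geometry (mm).
#' @param brain_axes_mm semi-axes of the brain ellipsoid (mm).
#' @param lesion_axes_mm,lesion_center_mm lesion ellipsoid semi-axes and
#'   centre (mm, relative to the brain centre; must stay inside the brain and
#'   inside the affected hemisphere).
#' @param lesion_t2_factor,lesion_t2star_factor multiplicative lesion
#'   contrast on the T2 / T2* volume (1.5 means +50% hyperintense).
#' @param tissue_intensity baseline tissue intensity (arbitrary units).
#' @param n_speckles number of planted cell-speckle sites.
#' @param speckle_contrast fractional intensity change of a speckle voxel,
#'   in (0, 1]; hypointense speckles are multiplied by `1 - speckle_contrast`.
#' @param hyper_speckle_fraction fraction of speckles made HYPERintense
#'   (confounders for the histogram classification step).
#' @param speckle_footprint `"single"` (one voxel) or `"cross"` (voxel plus
#'   its 6 face neighbours).
#' @param speckle_region_scale speckles are planted inside the lesion
#'   ellipsoid scaled by this factor ("in and around" the lesion).
#' @param min_speckle_sep_vox minimum Chebyshev distance between speckle
#'   sites (keeps planted clusters from merging).
#' @param bias_amplitude peak fractional deviation of the multiplicative
#'   bias field from its mean of 1.
#' @param noise_sigma additive noise SD as a fraction of `tissue_intensity`.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param rigid_transform inter-session misalignment applied to the second
#'   timepoint by [generate_phantom_pair()].
#' @param affected_side hemisphere carrying the lesion.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   phantoms.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(128L, 104L, 20L),
                           voxel_size_mm = c(14 / 128, 11 / 104, 1.0),
                           slice_thickness_mm = 0.8,
                           slice_gap_mm = 0.2,
                           brain_axes_mm = c(5.6, 4.4, 8.8),
                           lesion_axes_mm = c(2, 2.5, 3),
                           lesion_center_mm = c(2.8, 0.5, 0),
                           lesion_t2_factor = 1.5,
                           lesion_t2star_factor = 1.0,
                           tissue_intensity = 100,
                           n_speckles = 300L,
                           speckle_contrast = 0.5,
                           hyper_speckle_fraction = 0,
                           speckle_footprint = c("single", "cross"),
                           speckle_region_scale = 1.5,
                           min_speckle_sep_vox = 2L,
                           bias_amplitude = 0.1,
                           noise_sigma = 0.02,
                           noise_model = c("gaussian", "rician"),
                           rigid_transform = vsoptrack::rigid_transform(),
                           affected_side = "right",
                           seed = 1L) {
  cfg <- list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = as.numeric(voxel_size_mm),
    slice_thickness_mm = slice_thickness_mm, slice_gap_mm = slice_gap_mm,
    brain_axes_mm = as.numeric(brain_axes_mm),
    lesion_axes_mm = as.numeric(lesion_axes_mm),
    lesion_center_mm = as.numeric(lesion_center_mm),
    lesion_t2_factor = lesion_t2_factor,
    lesion_t2star_factor = lesion_t2star_factor,
    tissue_intensity = tissue_intensity,
    n_speckles = as.integer(n_speckles),
    speckle_contrast = speckle_contrast,
    hyper_speckle_fraction = hyper_speckle_fraction,
    speckle_footprint = match.arg(speckle_footprint),
    speckle_region_scale = speckle_region_scale,
    min_speckle_sep_vox = as.integer(min_speckle_sep_vox),
    bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
    noise_model = match.arg(noise_model),
    rigid_transform = rigid_transform,
    affected_side = match.arg(affected_side, c("left", "right")),
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (any(grid_shape < 4L)) stop("phantom_config: grid too small")
    if (any(voxel_size_mm <= 0) || any(brain_axes_mm <= 0) ||
        any(lesion_axes_mm <= 0)) {
      stop("phantom_config: dimensions must be positive")
    }
    if (abs(voxel_size_mm[3] - (slice_thickness_mm + slice_gap_mm)) > 1e-9) {
      stop("phantom_config: through-plane spacing must equal thickness + gap")
    }
    if (speckle_contrast <= 0 || speckle_contrast > 1) {
      stop("phantom_config: speckle_contrast must be in (0, 1]")
    }
    if (hyper_speckle_fraction < 0 || hyper_speckle_fraction > 1) {
      stop("phantom_config: hyper_speckle_fraction must be in [0, 1]")
    }
    if (n_speckles < 0) stop("phantom_config: n_speckles must be >= 0")
    if (noise_sigma < 0 || bias_amplitude < 0) {
      stop("phantom_config: noise_sigma and bias_amplitude must be >= 0")
    }
    # lesion strictly inside the brain ellipsoid: sample the lesion surface
    u <- surface_points(400L)
    pts <- sweep(sweep(u, 2, lesion_axes_mm, `*`), 2, lesion_center_mm, `+`)
    q <- rowSums(sweep(pts, 2, brain_axes_mm, `/`)^2)
    if (any(q >= 1)) stop("phantom_config: lesion ellipsoid not inside brain")
    # lesion confined to the affected hemisphere (x = 0 is the midline)
    sgn <- if (affected_side == "right") 1 else -1
    if (sgn * lesion_center_mm[1] - lesion_axes_mm[1] <= 0) {
      stop("phantom_config: lesion crosses the midline")
    }
  })
  invisible(cfg)
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
surface_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# mm coordinates of voxel centres relative to the grid centre
grid_coords_mm <- function(grid_shape, voxel_size_mm) {
  lapply(1:3, function(a) {
    (seq_len(grid_shape[a]) - (grid_shape[a] + 1) / 2) * voxel_size_mm[a]
  })
}

ellipsoid_mask <- function(coords, center_mm, axes_mm) {
  qx <- ((coords[[1]] - center_mm[1]) / axes_mm[1])^2
  qy <- ((coords[[2]] - center_mm[2]) / axes_mm[2])^2
  qz <- ((coords[[3]] - center_mm[3]) / axes_mm[3])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= 1
}

# deterministic structural geometry: masks and speckle sites
phantom_geometry <- function(cfg) {
  coords <- grid_coords_mm(cfg$grid_shape, cfg$voxel_size_mm)
  brain <- ellipsoid_mask(coords, c(0, 0, 0), cfg$brain_axes_mm)
  lesion <- ellipsoid_mask(coords, cfg$lesion_center_mm, cfg$lesion_axes_mm)
  lesion <- lesion & brain
  centroid_x <- sum(slice.index(brain, 1) * brain) / sum(brain)
  midline <- as.integer(round(centroid_x))
  sag <- slice.index(brain, 1)
  affected <- if (cfg$affected_side == "right") brain & sag > midline else
    brain & sag < midline
  if (!all(lesion[!affected] == FALSE)) {
    stop("phantom_config: lesion voxels outside the affected hemisphere")
  }

  region <- ellipsoid_mask(coords, cfg$lesion_center_mm,
                           cfg$lesion_axes_mm * cfg$speckle_region_scale)
  region <- region & affected
  cand <- which(region, arr.ind = TRUE)
  n <- cfg$n_speckles
  centers <- matrix(integer(0), 0, 3)
  if (n > 0L) {
    if (nrow(cand) < n) {
      stop("phantom_config: n_speckles exceeds available speckle-region voxels")
    }
    ord <- sample.int(nrow(cand))
    sep <- cfg$min_speckle_sep_vox
    kept <- matrix(0L, n, 3)
    k <- 0L
    for (i in ord) {
      p <- cand[i, ]
      if (k > 0L) {
        cheb <- pmax(abs(kept[seq_len(k), 1] - p[1]),
                     pmax(abs(kept[seq_len(k), 2] - p[2]),
                          abs(kept[seq_len(k), 3] - p[3])))
        if (min(cheb) < sep) next
      }
      k <- k + 1L
      kept[k, ] <- p
      if (k == n) break
    }
    if (k < n) {
      stop("phantom_config: speckle region too small for n_speckles at the requested separation")
    }
    centers <- kept
  }
  n_hyper <- round(cfg$hyper_speckle_fraction * n)
  hyper_idx <- if (n_hyper > 0L) sample.int(n, n_hyper) else integer(0)
  list(brain_mask = brain, lesion_mask = lesion, midline_plane = midline,
       centers_hypo = centers[setdiff(seq_len(n), hyper_idx), , drop = FALSE],
       centers_hyper = centers[hyper_idx, , drop = FALSE])
}

# expand speckle centres to their voxel footprint, clipped to the brain
speckle_voxels <- function(centers, footprint, brain) {
  if (nrow(centers) == 0L) return(matrix(integer(0), 0, 3))
  vox <- centers
  if (footprint == "cross") {
    offs <- neighbourhood_offsets(6L)
    ext <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
      sweep(centers, 2, offs[i, ], `+`)
    }))
    vox <- rbind(centers, ext)
  }
  d <- dim(brain)
  ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 & vox[, 2] <= d[2] &
    vox[, 3] >= 1 & vox[, 3] <= d[3]
  vox <- unique(vox[ok, , drop = FALSE])
  vox[brain[vox], , drop = FALSE]
}

#' Multiplicative bias field corruption
#'
#' Generates a smooth random polynomial field with mean exactly 1 over the
#' brain mask and maximal fractional deviation exactly `amplitude`, and
#' multiplies it into the volume. This is the corruption that the
#' preprocessing stage's bias-field correction is expected to undo.
#'
#' @param vol a [volume_image()].
#' @param amplitude peak |field - 1| over the mask (>= 0).
#' @param mask logical array over which the field is normalized (default:
#'   the whole grid).
#' @param order polynomial order of the random field.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return list with `vol` (corrupted volume) and `field` (the applied field
#'   as a [volume_image()]).
#' @export
apply_bias_field <- function(vol, amplitude, mask = NULL, order = 2L,
                             seed = NULL) {
  stopifnot(inherits(vol, "volume_image"))
  if (amplitude < 0) stop("apply_bias_field: amplitude must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, d)
  field <- make_bias_field(d, mask, amplitude, order)
  list(vol = with_data(vol, vol$data * field),
       field = with_data(vol, field))
}

make_bias_field <- function(dim3, mask, amplitude, order = 2L) {
  if (amplitude == 0) return(array(1, dim3))
  X <- poly_basis3(dim3, order)
  beta <- rnorm(ncol(X))
  beta[1] <- 0  # intercept carries no shape
  raw <- array(X %*% beta, dim3)
  raw <- raw - mean(raw[mask])
  peak <- max(abs(raw[mask]))
  if (peak == 0) return(array(1, dim3))
  1 + amplitude * raw / peak
}

add_noise <- function(arr, sigma_abs, model) {
  if (sigma_abs == 0) return(arr)
  d <- dim(arr)
  if (model == "rician") {
    n1 <- array(rnorm(length(arr), 0, sigma_abs), d)
    n2 <- array(rnorm(length(arr), 0, sigma_abs), d)
    sqrt((arr + n1)^2 + n2^2)
  } else {
    arr + array(rnorm(length(arr), 0, sigma_abs), d)
  }
}

# noiseless structural T2/T2* arrays from geometry + speckle lists
render_structure <- function(cfg, geo, vox_hypo, vox_hyper) {
  base <- ifelse(geo$brain_mask, cfg$tissue_intensity, 0)
  t2 <- base * ifelse(geo$lesion_mask, cfg$lesion_t2_factor, 1)
  t2s <- base * ifelse(geo$lesion_mask, cfg$lesion_t2star_factor, 1)
  if (nrow(vox_hypo) > 0L) t2s[vox_hypo] <- t2s[vox_hypo] * (1 - cfg$speckle_contrast)
  if (nrow(vox_hyper) > 0L) t2s[vox_hyper] <- t2s[vox_hyper] * (1 + cfg$speckle_contrast)
  list(t2 = t2, t2star = t2s)
}

# one imaging session: fresh bias field + fresh noise on both contrasts
render_session <- function(cfg, structure, brain, timepoint_label) {
  field <- make_bias_field(cfg$grid_shape, brain, cfg$bias_amplitude)
  sig <- cfg$noise_sigma * cfg$tissue_intensity
  mk <- function(arr) {
    volume_image(add_noise(arr * field, sig, cfg$noise_model),
                 cfg$voxel_size_mm, slice_axis = 3L,
                 slice_thickness_mm = cfg$slice_thickness_mm,
                 slice_gap_mm = cfg$slice_gap_mm,
                 timepoint_label = timepoint_label)
  }
  list(t2 = mk(structure$t2), t2star = mk(structure$t2star), field = field)
}

phantom_truth <- function(cfg, geo, vox_hypo, vox_hyper, field, transform) {
  structure(list(
    brain_mask = geo$brain_mask, lesion_mask = geo$lesion_mask,
    midline_plane = geo$midline_plane, affected_side = cfg$affected_side,
    centers_hypo = geo$centers_hypo, centers_hyper = geo$centers_hyper,
    speckle_voxels_hypo = vox_hypo, speckle_voxels_hyper = vox_hyper,
    bias_field = field, applied_transform = transform,
    lesion_volume_mm3 = 4 / 3 * pi * prod(cfg$lesion_axes_mm),
    voxel_size_mm = cfg$voxel_size_mm, grid_shape = cfg$grid_shape,
    speckle_footprint = cfg$speckle_footprint,
    min_speckle_sep_vox = cfg$min_speckle_sep_vox
  ), class = "phantom_truth")
}

#' Generate a synthetic T2/T2* phantom with ground truth
#'
#' @param config a [phantom_config()].
#' @return list with `t2`, `t2star` (both [volume_image()]) and `truth`
#'   (class `phantom_truth`: masks, speckle voxel lists, bias field, analytic
#'   lesion volume).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  geo <- phantom_geometry(config)
  vox_hypo <- speckle_voxels(geo$centers_hypo, config$speckle_footprint,
                             geo$brain_mask)
  vox_hyper <- speckle_voxels(geo$centers_hyper, config$speckle_footprint,
                              geo$brain_mask)
  struct <- render_structure(config, geo, vox_hypo, vox_hyper)
  ses <- render_session(config, struct, geo$brain_mask, "48h")
  list(t2 = ses$t2, t2star = ses$t2star,
       truth = phantom_truth(config, geo, vox_hypo, vox_hyper, ses$field,
                             rigid_transform()))
}

#' Generate a registered two-timepoint phantom pair
#'
#' Renders the same structural geometry at two sessions: the second session
#' can differ by migrated speckles ([migrate_speckles()]), is moved by the
#' config's `rigid_transform` (simulating repositioning between sessions),
#' and receives an independent bias field and noise draw.
#'
#' @param config a [phantom_config()].
#' @param n_move number of hypointense speckles relocated before the second
#'   session ("migration").
#' @param displacement_mm displacement applied to relocated speckles.
#' @return list with elements `tp1` and `tp2`, each as in
#'   [generate_phantom()]; `tp2$truth$applied_transform` records the planted
#'   misalignment.
#' @export
generate_phantom_pair <- function(config, n_move = 0L,
                                  displacement_mm = c(0, 0, 0)) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  geo <- phantom_geometry(config)
  fp <- config$speckle_footprint
  vox_hypo <- speckle_voxels(geo$centers_hypo, fp, geo$brain_mask)
  vox_hyper <- speckle_voxels(geo$centers_hyper, fp, geo$brain_mask)
  struct1 <- render_structure(config, geo, vox_hypo, vox_hyper)
  ses1 <- render_session(config, struct1, geo$brain_mask, "48h")
  truth1 <- phantom_truth(config, geo, vox_hypo, vox_hyper, ses1$field,
                          rigid_transform())

  truth2 <- truth1
  if (n_move > 0L) {
    truth2 <- migrate_speckles(truth1, n_move, displacement_mm)
  }
  geo2 <- geo
  geo2$centers_hypo <- truth2$centers_hypo
  vox_hypo2 <- speckle_voxels(geo2$centers_hypo, fp, geo$brain_mask)
  struct2 <- render_structure(config, geo2, vox_hypo2, vox_hyper)
  tr <- config$rigid_transform
  mk_clean <- function(arr) {
    volume_image(arr, config$voxel_size_mm, slice_axis = 3L,
                 slice_thickness_mm = config$slice_thickness_mm,
                 slice_gap_mm = config$slice_gap_mm)
  }
  moved <- list(
    t2 = apply_rigid(mk_clean(struct2$t2), tr)$data,
    t2star = apply_rigid(mk_clean(struct2$t2star), tr)$data
  )
  brain2 <- apply_rigid(mk_clean(ifelse(geo$brain_mask, 1, 0)), tr)$data > 0.5
  ses2 <- render_session(config, moved, brain2, "9d")
  truth2 <- phantom_truth(config, geo2, vox_hypo2, vox_hyper, ses2$field, tr)
  truth2$brain_mask_moved <- brain2
  list(tp1 = list(t2 = ses1$t2, t2star = ses1$t2star, truth = truth1),
       tp2 = list(t2 = ses2$t2, t2star = ses2$t2star, truth = truth2))
}

#' Relocate planted speckles between timepoints
#'
#' Emulates cell migration: `n_move` hypointense speckle sites are removed
#' from their original locations and re-planted at sites displaced by
#' `displacement_mm` (rounded to voxels). The total speckle count is
#' conserved. Re-planted sites must lie inside the brain and respect the
#' phantom's minimum speckle separation (cells migrate within tissue and a
#' re-planted deposit is a deposit like any other); speckles whose displaced
#' site satisfies both are preferred, and for the remainder the `on_outside`
#' policy applies: `"resample"` draws a random in-brain site at the required
#' separation, `"error"` aborts.
#'
#' @param truth a `phantom_truth`.
#' @param n_move number of speckles to move (<= number of hypo speckles).
#' @param displacement_mm 3-vector displacement (mm).
#' @param seed optional seed for the choice of which speckles move.
#' @param on_outside fallback when a displaced site is invalid.
#' @return updated `phantom_truth`.
#' @export
migrate_speckles <- function(truth, n_move, displacement_mm = c(0, 0, 0),
                             seed = NULL, on_outside = c("resample", "error")) {
  stopifnot(inherits(truth, "phantom_truth"))
  on_outside <- match.arg(on_outside)
  if (!is.null(seed)) set.seed(seed)
  n_move <- as.integer(n_move)
  if (n_move == 0L) return(truth)
  centers <- truth$centers_hypo
  n <- nrow(centers)
  if (n_move > n) {
    stop("migrate_speckles: n_move exceeds the number of hypointense speckles")
  }
  off <- round(displacement_mm / truth$voxel_size_mm)
  d <- truth$grid_shape
  brain <- truth$brain_mask
  sep <- truth$min_speckle_sep_vox %||% 1L
  all_centers <- rbind(centers, truth$centers_hyper)
  site_ok <- function(p, exclude_row) {
    if (any(p < 1L) || any(p > d) || !brain[p[1], p[2], p[3]]) return(FALSE)
    others <- all_centers[-exclude_row, , drop = FALSE]
    if (nrow(others) == 0L) return(TRUE)
    cheb <- pmax(abs(others[, 1] - p[1]),
                 pmax(abs(others[, 2] - p[2]), abs(others[, 3] - p[3])))
    min(cheb) >= sep
  }
  valid <- vapply(seq_len(n), function(i) {
    site_ok(centers[i, ] + off, i)
  }, logical(1))
  pick <- function(pool, k) if (length(pool) <= k) pool else sample(pool, k)
  move_idx <- pick(which(valid), n_move)
  if (length(move_idx) < n_move) {
    if (on_outside == "error") {
      stop("migrate_speckles: displaced site falls outside the brain or violates separation")
    }
    extra <- pick(setdiff(seq_len(n), move_idx), n_move - length(move_idx))
    move_idx <- c(move_idx, extra)
  }
  cand <- NULL
  for (i in move_idx) {
    p <- centers[i, ] + off
    if (!site_ok(p, i)) {
      # resample a random valid in-brain site
      if (is.null(cand)) cand <- which(brain, arr.ind = TRUE)
      found <- FALSE
      for (j in sample.int(nrow(cand), min(nrow(cand), 2000L))) {
        if (site_ok(cand[j, ], i)) {
          p <- cand[j, ]
          found <- TRUE
          break
        }
      }
      if (!found) stop("migrate_speckles: no valid re-plant site found")
    }
    centers[i, ] <- p
    all_centers[i, ] <- p
  }
  truth$centers_hypo <- centers
  truth$speckle_voxels_hypo <- speckle_voxels(centers, truth$speckle_footprint,
                                              brain)
  truth
}
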