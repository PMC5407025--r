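# a desk-sized phantom configuration: same anatomy proportions as the
# default geometry on a quarter-size grid, for fast unit tests
small_config <- function(seed = 1L, ...) {
  args <- list(
    grid_shape = c(64L, 52L, 12L),
    voxel_size_mm = c(14 / 64, 11 / 52, 1),
    brain_axes_mm = c(5.6, 4.4, 4.8),
    lesion_axes_mm = c(1.6, 2, 2.4),
    lesion_center_mm = c(2.6, 0.4, 0),
    n_speckles = 60L,
    seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_config, args)
}

# standard preprocessing chain on a generated phantom
preprocess_phantom <- function(ph, poly_order = 3L) {
  mask <- extract_brain(ph$t2)
  list(mask = mask,
       t2 = normalize_mean(correct_bias(ph$t2, mask, poly_order)$vol, mask),
       t2star = normalize_mean(correct_bias(ph$t2star, mask, poly_order)$vol, mask))
}

truth_speckle_mask <- function(truth, which = c("hypo", "hyper")) {
  which <- match.arg(which)
  vox <- if (which == "hypo") truth$speckle_voxels_hypo else truth$speckle_voxels_hyper
  m <- array(FALSE, truth$grid_shape)
  if (nrow(vox) > 0) m[vox] <- TRUE
  m
}

reflect_index <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# brute-force per-voxel median residual (reflective boundaries)
oracle_median_residual <- function(arr, k) {
  d <- dim(arr)
  r <- k %/% 2L
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    vals <- numeric(k^3)
    b <- 0L
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      b <- b + 1L
      vals[b] <- arr[reflect_index(x + dx, d[1]),
                     reflect_index(y + dy, d[2]),
                     reflect_index(z + dz, d[3])]
    }
    out[x, y, z] <- abs(arr[x, y, z] - median(vals))
  }
  out
}

# brute-force per-voxel local-statistics Wiener filter
oracle_wiener <- function(arr, k) {
  d <- dim(arr)
  r <- k %/% 2L
  mu <- array(0, d)
  s2 <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    vals <- numeric(k^3)
    b <- 0L
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      b <- b + 1L
      vals[b] <- arr[reflect_index(x + dx, d[1]),
                     reflect_index(y + dy, d[2]),
                     reflect_index(z + dz, d[3])]
    }
    mu[x, y, z] <- mean(vals)
    s2[x, y, z] <- mean(vals^2) - mean(vals)^2
  }
  s2 <- pmax(s2, 0)
  nu <- mean(s2)
  mu + pmax(s2 - nu, 0) / pmax(s2, nu) * (arr - mu)
}

# exhaustive-permutation two-sided Mann-Whitney p, written independently:
# midranks computed from pairwise comparisons, deviation of the rank sum
oracle_mw_p <- function(a, b) {
  x <- c(a, b)
  n <- length(x)
  na <- length(a)
  r <- vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
  w_obs <- sum(r[seq_len(na)])
  e_w <- na * (n + 1) / 2
  sets <- combn(n, na)
  w_all <- apply(sets, 2, function(ix) sum(r[ix]))
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# trapezoid-rule integration of the piecewise area profile: constant over
# each acquired slice, linear across each gap
oracle_slice_gap_volume <- function(areas, thickness, gap) {
  k <- length(areas)
  z <- numeric(0)
  a <- numeric(0)
  z0 <- 0
  for (i in seq_len(k)) {
    z <- c(z, z0, z0 + thickness)
    a <- c(a, areas[i], areas[i])
    z0 <- z0 + thickness + gap
  }
  pracma::trapz(z, a)
}
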