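test_that("slice-plus-gap volume matches hand arithmetic and its limits", {
  expect_equal(interpolated_volume(c(2, 4), 0.8, 0.2), 5.4, tolerance = 1e-12)
  expect_equal(interpolated_volume(7, 0.8, 0.2), 5.6, tolerance = 1e-12)
  areas <- c(1, 3, 2, 5)
  expect_equal(interpolated_volume(areas, 0.5, 0), sum(areas) * 0.5,
               tolerance = 1e-12)
  expect_error(interpolated_volume(c(1, -1), 0.8, 0.2), "negative")
  expect_error(interpolated_volume(numeric(0), 0.8, 0.2), "at least one")
  expect_error(interpolated_volume(1, 0, 0.2), "thickness")
})

test_that("slice-plus-gap volume equals trapezoid integration of the area profile", {
  set.seed(42)
  for (i in 1:100) {
    k <- sample(1:20, 1)
    areas <- runif(k, 0, 30)
    th <- runif(1, 0.1, 2)
    gap <- runif(1, 0, 1)
    got <- interpolated_volume(areas, th, gap)
    want <- oracle_slice_gap_volume(areas, th, gap)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("slice areas count in-plane voxels times voxel area", {
  vol <- volume_image(array(0, c(10, 10, 4)), c(0.1, 0.1, 1),
                      slice_thickness_mm = 0.8, slice_gap_mm = 0.2)
  lesion <- array(FALSE, c(10, 10, 4))
  lesion[1:5, 1:2, 2] <- TRUE  # 10 voxels on slice 2
  sa <- slice_areas(lesion, vol)
  expect_equal(sa$area_mm2, c(0, 0.1, 0, 0), tolerance = 1e-12)
  expect_equal(sa$slice_index, 1:4)
  empty <- slice_areas(lesion & FALSE, vol)
  expect_true(all(empty$area_mm2 == 0))
  bad <- array(FALSE, c(9, 10, 4))
  expect_error(slice_areas(bad, vol), "grid")
})

test_that("percentage and residual computations follow their definitions", {
  expect_equal(infarct_percent(5.4, 108), 5)
  expect_equal(infarct_percent(0, 108), 0)
  expect_equal(infarct_percent(108, 108), 100)
  expect_error(infarct_percent(1, 0), "brain volume")
  expect_equal(residual_percent(10, 10)$percent_of_48h, 100)
  expect_equal(residual_percent(10, 5)$percent_of_48h, 50)
  expect_error(residual_percent(0, 5), "baseline")
})

test_that("lesion segmentation recovers the planted lesion and respects the hemisphere", {
  ph <- generate_phantom(small_config(noise_sigma = 0.02))
  pp <- preprocess_phantom(ph)
  lesion <- segment_lesion(pp$t2, pp$mask)
  expect_gte(dice(lesion, ph$truth$lesion_mask), 0.9)
  hemi <- split_hemispheres(pp$mask)
  expect_true(all(hemi$affected[lesion]))
  # lesion-free phantom yields an empty mask with a warning
  ph0 <- generate_phantom(small_config(lesion_t2_factor = 1, n_speckles = 0L))
  pp0 <- preprocess_phantom(ph0)
  expect_warning(l0 <- segment_lesion(pp0$t2, pp0$mask), "empty lesion")
  expect_false(any(l0))
})

test_that("pipeline lesion volume approximates the analytic ellipsoid volume", {
  for (s in 1:2) {
    ph <- generate_phantom(small_config(noise_sigma = 0.05, seed = s))
    pp <- preprocess_phantom(ph)
    res <- infarct_volumetry(pp$t2, pp$mask)
    expect_lt(abs(res$lesion_volume_mm3 / ph$truth$lesion_volume_mm3 - 1), 0.1)
    expect_gt(res$infarct_percent, 0)
    expect_lte(res$lesion_volume_mm3, res$brain_volume_mm3)
  }
})

test_that("infarct percentage is stable under isotropic grid refinement", {
  base <- small_config(noise_sigma = 0.01, n_speckles = 0L)
  fine <- phantom_config(
    grid_shape = c(128L, 104L, 24L), voxel_size_mm = c(14 / 128, 11 / 104, 0.5),
    slice_thickness_mm = 0.4, slice_gap_mm = 0.1,
    brain_axes_mm = base$brain_axes_mm, lesion_axes_mm = base$lesion_axes_mm,
    lesion_center_mm = base$lesion_center_mm, n_speckles = 0L,
    noise_sigma = 0.01, seed = base$seed)
  pct <- sapply(list(base, fine), function(cfg) {
    ph <- generate_phantom(cfg)
    pp <- preprocess_phantom(ph)
    infarct_volumetry(pp$t2, pp$mask)$infarct_percent
  })
  expect_lt(abs(pct[2] / pct[1] - 1), 0.02)
})
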