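test_that("bias correction is near-identity on an unbiased phantom", {
  cfg <- small_config(n_speckles = 0L, bias_amplitude = 0, noise_sigma = 0,
                      lesion_t2_factor = 1)
  ph <- generate_phantom(cfg)
  mask <- extract_brain(ph$t2)
  bc <- correct_bias(ph$t2, mask)
  expect_lt(max(abs(bc$estimated_field$data[mask$mask] - 1)), 0.01)
})

test_that("bias correction restores homogeneous-tissue uniformity", {
  for (s in 1:3) {
    cfg <- small_config(n_speckles = 0L, bias_amplitude = 0,
                        noise_sigma = 0.01, seed = s)
    ph <- generate_phantom(cfg)
    corrupted <- apply_bias_field(ph$t2, amplitude = 0.2,
                                  mask = ph$truth$brain_mask, order = 1L,
                                  seed = 100 + s)$vol
    mask <- extract_brain(corrupted)
    bc <- correct_bias(corrupted, mask, poly_order = 2L)
    tissue <- ph$truth$brain_mask & !ph$truth$lesion_mask
    cv <- sd(bc$vol$data[tissue]) / mean(bc$vol$data[tissue])
    expect_lt(cv, 0.02)
    # mask mean preserved, voxels outside the mask untouched
    expect_equal(mean(bc$vol$data[mask$mask]), mean(corrupted$data[mask$mask]),
                 tolerance = 1e-3)
    expect_identical(bc$vol$data[!mask$mask], corrupted$data[!mask$mask])
    expect_true(all(is.finite(bc$vol$data)))
  }
})

test_that("bias correction rejects an underdetermined fit", {
  cfg <- small_config(n_speckles = 0L)
  ph <- generate_phantom(cfg)
  tiny <- array(FALSE, dim(ph$t2$data))
  tiny[30:33, 25:27, 6] <- TRUE
  expect_error(correct_bias(ph$t2, brain_mask(tiny, 32L), poly_order = 3L),
               "mask too small")
})

test_that("brain extraction recovers the phantom brain mask", {
  ph0 <- generate_phantom(small_config(noise_sigma = 0))
  expect_gte(dice(extract_brain(ph0$t2)$mask, ph0$truth$brain_mask), 0.98)
  ph5 <- generate_phantom(small_config(noise_sigma = 0.05))
  m5 <- extract_brain(ph5$t2)
  expect_gte(dice(m5$mask, ph5$truth$brain_mask), 0.95)
  # midline lands at the sagittal centroid of a centred brain
  expect_equal(m5$midline_plane, 32L, tolerance = 1)
  zero <- volume_image(array(0, c(16, 16, 4)), c(1, 1, 1))
  expect_error(extract_brain(zero), "empty segmentation")
})

test_that("mean normalization is exact, idempotent and scale-invariant", {
  ph <- generate_phantom(small_config())
  mask <- extract_brain(ph$t2)
  n1 <- normalize_mean(ph$t2, mask)
  expect_equal(mean(n1$data[mask$mask]), 1000, tolerance = 1e-6)
  n2 <- normalize_mean(n1, mask)
  expect_equal(n2$data, n1$data, tolerance = 1e-9)
  scaled <- normalize_mean(with_data(ph$t2, ph$t2$data * 17), mask)
  expect_equal(scaled$data, n1$data, tolerance = 1e-9)
  neg <- with_data(ph$t2, ph$t2$data - 1e6)
  expect_error(normalize_mean(neg, mask), "nonpositive")
})

test_that("rigid registration recovers identity and planted transforms", {
  ph <- generate_phantom(phantom_config(seed = 5, n_speckles = 100L))
  # fixed == moving: identity within 0.1 voxel / 0.1 degree
  reg0 <- register_rigid(ph$t2star, ph$t2star)
  expect_lt(max(abs(reg0$transform$rotation_deg)), 0.1)
  expect_lt(max(abs(reg0$transform$translation_vox)), 0.1)
  # planted in-plane translation recovered within 0.5 voxel
  planted_t <- rigid_transform(translation_vox = c(2, 1, 0))
  regt <- register_rigid(apply_rigid(ph$t2star, planted_t), ph$t2star)
  invt <- invert_rigid(regt$transform, ph$t2star$voxel_size_mm)
  expect_lt(max(abs(invt$translation_vox - c(2, 1, 0))), 0.5)
  # planted in-plane rotation recovered within 1 degree
  planted_r <- rigid_transform(rotation_deg = c(0, 0, 5))
  regr <- register_rigid(apply_rigid(ph$t2star, planted_r), ph$t2star)
  invr <- invert_rigid(regr$transform, ph$t2star$voxel_size_mm)
  expect_lt(max(abs(invr$rotation_deg - c(0, 0, 5))), 1)
})
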