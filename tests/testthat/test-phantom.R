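test_that("phantom generation is deterministic and structurally sound", {
  cfg <- small_config(seed = 7)
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$t2$data, ph2$t2$data)
  expect_identical(ph1$t2star$data, ph2$t2star$data)
  expect_identical(ph1$truth$centers_hypo, ph2$truth$centers_hypo)

  truth <- ph1$truth
  expect_true(all(is.finite(ph1$t2$data)))
  expect_true(all(truth$brain_mask[truth$speckle_voxels_hypo]))
  expect_true(all(truth$brain_mask[truth$lesion_mask]))
  # lesion confined to one hemisphere (right of the midline)
  les <- which(truth$lesion_mask, arr.ind = TRUE)
  expect_true(all(les[, 1] > truth$midline_plane))
  # planted speckle count bookkeeping
  expect_identical(nrow(truth$centers_hypo) + nrow(truth$centers_hyper),
                   cfg$n_speckles)
})

test_that("structure-free phantom is constant over the brain", {
  cfg <- small_config(n_speckles = 0L, bias_amplitude = 0, noise_sigma = 0,
                      lesion_t2_factor = 1, lesion_t2star_factor = 1)
  ph <- generate_phantom(cfg)
  vals <- ph$t2star$data[ph$truth$brain_mask]
  expect_equal(max(vals) - min(vals), 0)
  expect_true(all(ph$t2star$data[!ph$truth$brain_mask] == 0))
})

test_that("analytic lesion volume matches the closed-form ellipsoid volume", {
  cfg <- small_config(lesion_axes_mm = c(2, 2, 2), lesion_center_mm = c(2.6, 0, 0))
  ph <- generate_phantom(cfg)
  expect_equal(ph$truth$lesion_volume_mm3, 4 / 3 * pi * 8, tolerance = 1e-12)
  # voxelized mask volume agrees within a surface-voxel margin
  vox_vol <- prod(cfg$voxel_size_mm)
  mask_vol <- sum(ph$truth$lesion_mask) * vox_vol
  surface <- sum(ph$truth$lesion_mask &
                   !erode3(ph$truth$lesion_mask, connectivity = 6L))
  expect_lt(abs(mask_vol - ph$truth$lesion_volume_mm3), 3 * vox_vol * surface)
})

test_that("bias field has mean one over the mask and the requested amplitude", {
  cfg <- small_config(n_speckles = 0L, noise_sigma = 0, bias_amplitude = 0)
  ph <- generate_phantom(cfg)
  mask <- ph$truth$brain_mask
  # amplitude zero: identity field
  bf0 <- apply_bias_field(ph$t2, amplitude = 0, mask = mask, seed = 1)
  expect_identical(bf0$vol$data, ph$t2$data)
  expect_true(all(bf0$field$data == 1))
  for (s in 1:10) {
    bf <- apply_bias_field(ph$t2, amplitude = 0.2, mask = mask, seed = s)
    f <- bf$field$data
    expect_equal(mean(f[mask]), 1, tolerance = 1e-6)
    expect_gte(max(abs(f[mask] - 1)), 0.15)
    expect_lte(max(abs(f[mask] - 1)), 0.25)
    expect_true(all(f > 0))
    expect_equal(bf$vol$data, ph$t2$data * f)
  }
  expect_error(apply_bias_field(ph$t2, amplitude = -0.1), "amplitude")
})

test_that("rigid resampling honours identity, inversion and rotational symmetry", {
  cfg <- small_config(n_speckles = 0L, noise_sigma = 0.01)
  ph <- generate_phantom(cfg)
  # identity is bit-exact
  expect_identical(apply_rigid(ph$t2, rigid_transform())$data, ph$t2$data)
  # translation and its inverse compose to the identity in the interior
  fwd <- apply_rigid(ph$t2, rigid_transform(translation_vox = c(2, 0, 0)))
  back <- apply_rigid(fwd, rigid_transform(translation_vox = c(-2, 0, 0)))
  interior <- ph$t2$data[4:61, 4:49, 2:11]
  expect_lt(max(abs(back$data[4:61, 4:49, 2:11] - interior)), 1e-6)
  # a sphere is invariant under rotation about its centre
  sph_cfg <- small_config(n_speckles = 0L, noise_sigma = 0,
                          bias_amplitude = 0, lesion_t2_factor = 1,
                          brain_axes_mm = c(4, 4, 4),
                          lesion_axes_mm = c(1.2, 1.2, 1.2),
                          lesion_center_mm = c(1.8, 0, 0))
  sph <- generate_phantom(sph_cfg)
  rot <- apply_rigid(sph$t2, rigid_transform(rotation_deg = c(0, 0, 10)))
  expect_gte(dice(rot$data > 50, sph$t2$data > 50), 0.99)
  # preconditions
  expect_error(apply_rigid(ph$t2, rigid_transform(rotation_deg = c(31, 0, 0))),
               "rotation")
  expect_error(apply_rigid(ph$t2, rigid_transform(translation_vox = c(40, 0, 0))),
               "translation")
})

test_that("speckle migration conserves counts and moves exactly n_move sites", {
  cfg <- small_config(n_speckles = 20L, min_speckle_sep_vox = 4L)
  truth <- generate_phantom(cfg)$truth
  expect_identical(migrate_speckles(truth, 0L), truth)
  for (k in c(1L, 3L, 5L)) {
    moved <- migrate_speckles(truth, k, displacement_mm = c(0, -1.2, 0),
                              seed = 11L)
    old_keys <- apply(truth$centers_hypo, 1, paste, collapse = ",")
    new_keys <- apply(moved$centers_hypo, 1, paste, collapse = ",")
    expect_identical(nrow(moved$centers_hypo), nrow(truth$centers_hypo))
    expect_identical(length(setdiff(old_keys, new_keys)), as.integer(k))
    expect_identical(length(setdiff(new_keys, old_keys)), as.integer(k))
    expect_true(all(truth$brain_mask[moved$centers_hypo]))
  }
  expect_error(migrate_speckles(truth, 100L), "n_move")
})

test_that("invalid phantom configurations are rejected", {
  expect_error(small_config(lesion_center_mm = c(5, 0, 0)), "inside brain")
  expect_error(small_config(lesion_center_mm = c(1, 0, 0)), "midline")
  expect_error(small_config(speckle_contrast = 0), "speckle_contrast")
  expect_error(small_config(hyper_speckle_fraction = 1.5), "hyper_speckle_fraction")
  expect_error(generate_phantom(small_config(n_speckles = 50000L)), "speckle")
})
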