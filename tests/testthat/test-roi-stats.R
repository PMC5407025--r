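test_that("hemisphere split partitions the brain with a contralateral tie-break", {
  ph <- generate_phantom(small_config())
  mask <- extract_brain(ph$t2)
  hemi <- split_hemispheres(mask)
  expect_false(any(hemi$affected & hemi$contralateral))
  expect_identical(hemi$affected | hemi$contralateral, mask$mask)
  # midline-plane voxels are contralateral
  sag <- slice.index(mask$mask, 1)
  expect_true(all(hemi$contralateral[sag == mask$midline_plane] ==
                    mask$mask[sag == mask$midline_plane]))
  # a symmetric brain splits nearly evenly
  expect_lt(abs(sum(hemi$affected) - sum(hemi$contralateral)),
            sum(mask$mask & sag == mask$midline_plane) + 1)
  # lesion voxels of a right-sided-lesion phantom fall in the affected half
  expect_true(all(hemi$affected[ph$truth$lesion_mask]))
})

test_that("ROI moments reproduce hand-computed mean and sample SD", {
  vol <- volume_image(array(0, c(3, 3, 1)), c(1, 1, 1))
  roi <- array(FALSE, c(3, 3, 1))
  roi[1:3, 1, 1] <- TRUE
  vol$data[1:3, 1, 1] <- c(1, 2, 3)
  m <- roi_moments(vol, roi)
  expect_equal(m$mean, 2)
  expect_equal(m$sd, 1)
  vol$data[1:3, 1, 1] <- c(2, 4, 6)
  m <- roi_moments(vol, roi)
  expect_equal(m$mean, 4)
  expect_equal(m$sd, 2)
  vol$data[1:3, 1, 1] <- 5
  m <- roi_moments(vol, roi)
  expect_equal(m$sd, 0)
  roi1 <- roi & FALSE
  roi1[1, 1, 1] <- TRUE
  expect_error(roi_moments(vol, roi1), "at least 2")
})

test_that("slice delta-CSI is the root-sum-of-squares of the hemisphere CVs", {
  rs <- function(mean, sd) structure(list(mean = mean, sd = sd, n_voxels = 10L),
                                     class = "roi_stats")
  expect_equal(slice_delta_csi(rs(100, 0), rs(200, 0)), 0)
  expect_equal(slice_delta_csi(rs(100, 10), rs(200, 0)), 0.1, tolerance = 1e-9)
  expect_equal(slice_delta_csi(rs(4, 2), rs(2, 1)), sqrt(0.5), tolerance = 1e-9)
  expect_equal(slice_delta_csi(rs(50, 25), rs(50, 25)), sqrt(2) / 2,
               tolerance = 1e-9)
  expect_error(slice_delta_csi(rs(0, 1), rs(2, 1)), "nonpositive")
})

test_that("animal delta-CSI vanishes on a structure-free phantom and is scale-invariant", {
  cfg <- small_config(n_speckles = 0L, bias_amplitude = 0, noise_sigma = 0,
                      lesion_t2star_factor = 1)
  ph <- generate_phantom(cfg)
  mask <- brain_mask(ph$truth$brain_mask, ph$truth$midline_plane)
  d0 <- animal_delta_csi(ph$t2star, mask)
  expect_equal(d0$mean_dcsi, 0, tolerance = 1e-9)
  expect_identical(d0$n_slices, 7L)

  ph2 <- generate_phantom(small_config())
  mask2 <- extract_brain(ph2$t2)
  d1 <- animal_delta_csi(ph2$t2star, mask2, lesion_mask = ph2$truth$lesion_mask)
  d2 <- animal_delta_csi(with_data(ph2$t2star, ph2$t2star$data * 3.7), mask2,
                         lesion_mask = ph2$truth$lesion_mask)
  expect_equal(d2$mean_dcsi, d1$mean_dcsi, tolerance = 1e-9)
  expect_equal(d2$per_slice$dcsi, d1$per_slice$dcsi, tolerance = 1e-9)
  expect_true(all(d1$per_slice$dcsi >= 0))
  # explicit slice selection is honoured
  d3 <- animal_delta_csi(ph2$t2star, mask2, slice_indices = 4:8)
  expect_identical(d3$per_slice$slice_index, 4:8)
})

test_that("mean delta-CSI grows with the planted speckle load", {
  doses <- c(0L, 60L, 200L)
  means <- sapply(doses, function(ns) {
    mean(sapply(1:3, function(s) {
      ph <- generate_phantom(small_config(n_speckles = ns, seed = s))
      pp <- preprocess_phantom(ph)
      animal_delta_csi(pp$t2star, pp$mask,
                       lesion_mask = ph$truth$lesion_mask)$mean_dcsi
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("exact Mann-Whitney enumeration matches hand values and the permutation oracle", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4)),
               list(U = 0, p_two_sided = 1 / 3), tolerance = 1e-12)
  same <- mann_whitney_u(c(1, 2, 3), c(3, 2, 1))
  expect_gte(same$p_two_sided, 0.99)
  set.seed(99)
  for (i in 1:8) {
    na <- sample(1:5, 1)
    nb <- sample(1:5, 1)
    a <- sample(1:4, na, replace = TRUE)  # replace=TRUE provokes ties
    b <- sample(1:4, nb, replace = TRUE)
    got <- mann_whitney_u(a, b)
    expect_equal(got$p_two_sided, oracle_mw_p(a, b), tolerance = 1e-12)
  }
  # untied exact branch agrees with the distribution-based reference
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(0.5, 4.4, 6.2, 7.7, 2.9)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  got <- mann_whitney_u(a, b)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("large-sample Mann-Whitney branch approximates the exact p", {
  set.seed(7)
  a <- rnorm(10)
  b <- rnorm(10, mean = 1.5)
  approx_p <- mann_whitney_u(a, b)$p_two_sided
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(approx_p, ref, tolerance = 1e-6)
})
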