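make_vol <- function(arr) volume_image(arr, c(1, 1, 1))

test_that("median residual isolates impulses and cancels smooth structure", {
  const <- make_vol(array(5, c(8, 8, 4)))
  expect_true(all(median_residual(const)$data == 0))
  # single impulse: residual equals the impulse height at its voxel only
  imp <- array(10, c(9, 9, 5))
  imp[5, 5, 3] <- 60
  r <- median_residual(make_vol(imp))$data
  expect_equal(r[5, 5, 3], 50)
  r[5, 5, 3] <- 0
  expect_true(all(r == 0))
  # linear ramp: interior residuals vanish (median of symmetric neighbourhoods)
  ramp <- array(rep(1:10, 10 * 4), c(10, 10, 4))
  rr <- median_residual(make_vol(ramp))$data
  expect_true(all(rr[2:9, 2:9, 2:3] == 0))
  expect_error(median_residual(const, 4), "odd")
})

test_that("median residual matches the brute-force oracle", {
  set.seed(1)
  arr <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_lt(max(abs(median_residual(make_vol(arr))$data -
                      oracle_median_residual(arr, 3))), 1e-10)
  arr2 <- array(sample(0:9, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  expect_lt(max(abs(median_residual(make_vol(arr2), 5)$data -
                      oracle_median_residual(arr2, 5))), 1e-10)
})

test_that("Wiener filter matches the brute-force oracle and reduces noise", {
  const <- make_vol(array(3, c(6, 6, 4)))
  expect_true(all(wiener_denoise(const)$data == 3))
  set.seed(2)
  arr <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_lt(max(abs(wiener_denoise(make_vol(arr))$data -
                      oracle_wiener(arr, 3))), 1e-10)
  for (s in 1:10) {
    set.seed(s)
    noise <- array(rnorm(12 * 12 * 6), c(12, 12, 6))
    expect_lt(var(as.vector(wiener_denoise(make_vol(noise))$data)),
              var(as.vector(noise)))
  }
  expect_error(wiener_denoise(const, 2), "odd")
})

test_that("speckle threshold is mean + 2 sample SD with a strict inequality", {
  arr <- array(0, c(5, 2, 1))
  arr[5, 2, 1] <- 30
  hemi <- array(TRUE, c(5, 2, 1))
  ts <- threshold_speckles(make_vol(arr), hemi)
  expect_equal(ts$threshold, 3 + 2 * sqrt(90), tolerance = 1e-12)
  expect_identical(which(ts$mask), which(arr == 30))
  # constant hemisphere: threshold equals the constant, mask empty
  tc <- threshold_speckles(make_vol(array(7, c(4, 4, 2))),
                           array(TRUE, c(4, 4, 2)))
  expect_equal(tc$threshold, 7)
  expect_false(any(tc$mask))
  expect_true(all(ts$mask[!hemi] == FALSE))
  expect_error(threshold_speckles(make_vol(arr), hemi & FALSE), ">= 2")
})

test_that("hypointense classification keeps the low mode and guards degenerate sets", {
  d <- c(10, 1, 1)
  orig <- make_vol(array(1000, d))
  none <- array(FALSE, d)
  expect_false(any(classify_hypointense(none, orig, 1000)))
  # separated bimodal set: exactly the low mode survives
  orig$data[1:10] <- c(rep(800, 5), rep(1200, 5))
  all10 <- array(TRUE, d)
  keep <- classify_hypointense(all10, orig, 1000)
  expect_identical(which(keep), 1:5L)
  # entirely hyperintense set: nothing survives
  orig$data[1:10] <- seq(1100, 1400, length.out = 10)
  expect_false(any(classify_hypointense(all10, orig, 1000)))
  # entirely hypointense unimodal set: everything survives
  orig$data[1:10] <- seq(480, 520, length.out = 10)
  expect_true(all(classify_hypointense(all10, orig, 1000)))
})

test_that("speckle map recovers planted speckles with nested masks", {
  ph <- generate_phantom(small_config(n_speckles = 60L))
  pp <- preprocess_phantom(ph)
  sm <- build_speckle_map(pp$t2star, pp$mask)
  hemi <- split_hemispheres(pp$mask)
  expect_true(all(hemi$affected[sm$speckled_mask]))
  expect_true(all(sm$speckled_mask[sm$hypo_mask]))
  expect_identical(sm$voxel_count, sum(sm$hypo_mask))
  expect_identical(sum(vapply(sm$clusters, `[[`, integer(1), "size")),
                   sm$voxel_count)
  truth <- truth_speckle_mask(ph$truth, "hypo")
  tp <- sum(sm$hypo_mask & truth)
  expect_gte(tp / sum(truth), 0.9)
  expect_gte(tp / sm$voxel_count, 0.9)
  # voxel count invariant to global rescaling before normalization
  scaled <- with_data(ph$t2star, ph$t2star$data * 4.2)
  sc <- normalize_mean(correct_bias(scaled, pp$mask)$vol, pp$mask)
  expect_identical(build_speckle_map(sc, pp$mask)$voxel_count, sm$voxel_count)
})

test_that("detection sensitivity does not decrease with speckle contrast", {
  sens <- sapply(c(0.1, 0.3, 0.5), function(ctr) {
    mean(sapply(1:3, function(s) {
      ph <- generate_phantom(small_config(speckle_contrast = ctr, seed = s))
      pp <- preprocess_phantom(ph)
      sm <- build_speckle_map(pp$t2star, pp$mask)
      truth <- truth_speckle_mask(ph$truth, "hypo")
      sum(sm$hypo_mask & truth) / sum(truth)
    }))
  })
  expect_true(all(diff(sens) >= 0))
  expect_gte(sens[3], 0.9)
})

test_that("timepoint comparison reports identical maps as unchanged", {
  ph <- generate_phantom(small_config())
  pp <- preprocess_phantom(ph)
  sm <- build_speckle_map(pp$t2star, pp$mask)
  cm <- compare_timepoints(sm, sm)
  expect_equal(cm$change_pct, 0)
  expect_identical(cm$n_appeared, 0L)
  expect_identical(cm$n_disappeared, 0L)
  expect_identical(nrow(cm$matched), length(sm$clusters))
  bad <- sm
  bad$hypo_mask <- bad$hypo_mask[1:10, , , drop = FALSE]
  expect_error(compare_timepoints(sm, bad), "grids")
})
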