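test_that("published threshold formulas reproduce their worked examples", {
  expect_equal(threshold_biehl_pct(1), 59.1)
  expect_equal(threshold_biehl_pct(10), 59.1 - 18.5)
  expect_equal(threshold_black(0), 0.588)
  expect_equal(threshold_black(4), 0.307 * 4 + 0.588)
  expect_equal(threshold_nestle(10, 1), 2.5)
  expect_equal(threshold_nestle(0, 1.3), 1.3)
  expect_equal(threshold_schaefer_fraction(1, 0, 1, "large"), 0.5)
  expect_equal(threshold_schaefer_fraction(6, 1, 8, "small"),
               (0.67 * 6 + 0.60 * 1) / 8)   # 0.5775
  # monotonicity: larger volume lowers the percentage, more background
  # raises the contrast-oriented fraction
  expect_lt(threshold_biehl_pct(20), threshold_biehl_pct(5))
  expect_gt(threshold_schaefer_fraction(6, 2, 8, "small"),
            threshold_schaefer_fraction(6, 1, 8, "small"))
})

test_that("threshold masks are the seed component of the supra-threshold set", {
  img <- two_level_volume(c(20, 10, 10), lesion = 3:6, level = 10)
  img$values[14:17, 3:6, 3:6] <- 10        # second, disjoint blob
  m <- mask_from_threshold(img, 5, c(4, 4, 4))
  expect_true(all(which(m$values, arr.ind = TRUE)[, 1] <= 6))
  expect_equal(sum(m$values), 4^3)
  # bit-exact recheck of the defining identity
  supra <- img$values >= 5
  expect_true(all(supra[m$values]))
  # entire grid for a threshold at or below the minimum
  all_m <- mask_from_threshold(img, min(img$values), c(4, 4, 4))
  expect_true(all(all_m$values))
  # empty-mask signal (not an error) above the maximum
  none <- mask_from_threshold(img, 11, c(4, 4, 4))
  expect_false(any(none$values))
})

test_that("percentage-of-maximum segmentation is exact on a binary image and nested in its fraction", {
  img <- two_level_volume(level = 10, background = 0)
  r <- segment_pct_max(img, c(7, 7, 7), fraction = 0.4)
  expect_equal(r$threshold, 4)
  expect_identical(r$mask$values, img$values == 10)
  r50 <- segment_pct_max(img, c(7, 7, 7), fraction = 0.5)
  expect_true(all(!r50$mask$values | r$mask$values))  # 0.5 mask within 0.4 mask
  flat <- pet_volume(array(2, c(5, 5, 5)), 2)
  expect_error(segment_pct_max(flat, c(2, 2, 2)), "flat")
})

test_that("signal-adaptive thresholding reaches its closed-form fixed point on a two-level image", {
  img <- two_level_volume(level = 8, background = 0.2)
  r <- segment_black(img, c(7, 7, 7))
  expect_true(r$converged)
  expect_lte(r$iterations, 2)              # two-level image: immediate fix
  expect_equal(r$threshold, 0.307 * 8 + 0.588, tolerance = 1e-6)
  expect_identical(r$mask$values, img$values == 8)
})

test_that("volume-adaptive thresholding converges and is monotone in lesion size", {
  small <- sphere_case(radius_mm = 10, grid = 40, blur = 6)
  large <- sphere_case(radius_mm = 18, grid = 48, blur = 6)
  ps <- prepared_case(small); pl <- prepared_case(large)
  rs <- segment_biehl(ps$pre, ps$seed_point)
  rl <- segment_biehl(pl$pre, pl$seed_point)
  expect_true(rs$converged && rl$converged)
  # Eq. is decreasing in volume: the larger lesion gets the lower %T
  expect_lt(rl$threshold / max(pl$pre$values),
            rs$threshold / max(ps$pre$values))
})

test_that("background-corrected thresholding matches two-level arithmetic", {
  img <- two_level_volume(c(20, 20, 20), lesion = 8:13, level = 8,
                          background = 1)
  bkg <- pet_mask(array(FALSE, c(20, 20, 20)), 2)
  bkg$values[1:3, 1:3, 1:3] <- TRUE
  r <- segment_nestle(img, c(10, 10, 10), bkg)
  # I_mean over the 70% isocontour of a uniform lesion is the lesion level
  expect_equal(r$threshold, 0.15 * 8 + 1, tolerance = 1e-9)
  expect_identical(r$mask$values, img$values == 8)
})

test_that("contrast-oriented thresholding picks size-dependent coefficients", {
  img <- two_level_volume(c(26, 26, 26), lesion = 5:22, level = 8,
                          background = 1)    # 36 mm cube: large class
  bkg <- pet_mask(array(FALSE, c(26, 26, 26)), 2)
  bkg$values[1:2, 1:2, 24:26] <- TRUE
  r <- segment_schaefer(img, c(13, 13, 13), bkg)
  expect_equal(r$threshold, (0.5 * 8 + 0.5 * 1) / 8 * 8, tolerance = 1e-9)
  small <- two_level_volume(c(20, 20, 20), lesion = 9:12, level = 8,
                            background = 1)  # 8 mm cube: small class
  bkg2 <- pet_mask(array(FALSE, c(20, 20, 20)), 2)
  bkg2$values[1:2, 1:2, 1:2] <- TRUE
  r2 <- segment_schaefer(small, c(10, 10, 10), bkg2)
  expect_equal(r2$threshold, 0.67 * 8 + 0.60 * 1, tolerance = 1e-9)
})

test_that("intensity scaling preserves the percentage rules but not the SUV-offset rules", {
  ph <- sphere_case(radius_mm = 12, grid = 40, blur = 6)
  pc <- prepared_case(ph)
  scaled <- pet_volume(3 * pc$pre$values, pc$pre$spacing, "suv")
  # percent-of-max masks are scale invariant
  m1 <- segment_pct_max(pc$pre, pc$seed_point)$mask
  m2 <- segment_pct_max(scaled, pc$seed_point)$mask
  expect_identical(m1$values, m2$values)
  b1 <- segment_biehl(pc$pre, pc$seed_point)$mask
  b2 <- segment_biehl(scaled, pc$seed_point)$mask
  expect_identical(b1$values, b2$values)
  # the additive-offset rule is not scale invariant
  k1 <- segment_black(pc$pre, pc$seed_point)$mask
  k2 <- segment_black(scaled, pc$seed_point)$mask
  expect_false(identical(k1$values, k2$values))
})

test_that("the background shell sits at the stated distance from the lesion box", {
  ph <- sphere_case(radius_mm = 10, grid = 48, blur = 0)
  shell <- background_shell(ph$truth, inner_mm = 15, outer_mm = 25)
  expect_gt(sum(shell$values), 0)
  expect_false(any(shell$values & ph$truth$values))
  idx <- which(ph$truth$values, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  box <- array(FALSE, dim(ph$truth$values))
  box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  d <- sqrt(petseg:::cpp_edt(as.logical(box), dim(box), ph$truth$spacing))
  expect_true(all(d[shell$values] >= 15 & d[shell$values] <= 25))
})
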