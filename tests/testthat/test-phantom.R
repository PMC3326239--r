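test_that("truth-mask volume matches the analytic sphere volume", {
  analytic <- 4 / 3 * pi * 1.5^3          # 15 mm radius, cm^3
  spec <- phantom_spec(grid_shape = c(40, 40, 40), spacing = 1,
                       background_uptake = 0,
                       components = lesion_component("sphere", c(20, 20, 20),
                                                     15, 8),
                       blur_fwhm = 0, noise_sigma = 0)
  ph <- make_phantom(spec)
  expect_lt(abs(mask_volume_cm3(ph$truth) - analytic) / analytic, 0.02)
})

test_that("voxel-centre volume converges to the analytic volume as spacing shrinks", {
  analytic <- 4 / 3 * pi * 1^3            # 10 mm radius
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    n <- as.integer(30 / sp)
    spec <- phantom_spec(grid_shape = rep(n, 3), spacing = sp,
                         background_uptake = 0,
                         components = lesion_component("sphere", rep(15, 3),
                                                       10, 5),
                         blur_fwhm = 0, noise_sigma = 0)
    abs(mask_volume_cm3(make_phantom(spec)$truth) - analytic) / analytic
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.005)
})

test_that("no blur and no noise reproduces the piecewise-constant uptake map", {
  spec <- phantom_spec(grid_shape = c(20, 20, 20), spacing = 2,
                       background_uptake = 1,
                       components = lesion_component("sphere", c(20, 20, 20),
                                                     8, 6),
                       blur_fwhm = 0, noise_sigma = 0)
  ph <- make_phantom(spec)
  expect_setequal(unique(as.numeric(ph$image$values)), c(1, 6))
  expect_identical(ph$image$values == 6, ph$truth$values)
})

test_that("phantom generation is deterministic and noise never alters the truth", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24), spacing = 2,
                       background_uptake = 2,
                       components = lesion_component("sphere", c(24, 24, 24),
                                                     9, 8),
                       blur_fwhm = 6, noise_sigma = 0.3, seed = 7)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$truth$values, b$truth$values)
  clean <- make_phantom(phantom_spec(grid_shape = c(24, 24, 24), spacing = 2,
                                     background_uptake = 2,
                                     components = spec$components,
                                     blur_fwhm = 0, noise_sigma = 0))
  expect_identical(a$truth$values, clean$truth$values)
})

test_that("degenerate specs and invalid components are rejected", {
  expect_error(phantom_spec(components = list(
    lesion_component("sphere", c(10, 10, 10), 5, 1)), background_uptake = 2),
    "above background")
  spec <- phantom_spec(grid_shape = c(10, 10, 10), spacing = 1,
                       background_uptake = 0,
                       components = lesion_component("sphere", c(500, 500, 500),
                                                     3, 5),
                       blur_fwhm = 0, noise_sigma = 0)
  expect_error(make_phantom(spec), "degenerate")
  expect_error(lesion_component("sphere", c(0, 0, 0), -1, 5), "radii")
})

test_that("system blur conserves intensity, is identity at zero, and has the stated FWHM", {
  img <- two_level_volume(c(25, 25, 25), lesion = 11:15, level = 9,
                          background = 1)
  expect_identical(apply_system_blur(img, 0)$values, img$values)
  blurred <- apply_system_blur(img, 6)
  expect_lt(abs(sum(blurred$values) - sum(img$values)) / sum(img$values),
            0.001)
  # delta spike: measured profile FWHM within half a voxel of 6 mm
  spike <- pet_volume(array(0, c(31, 31, 31)), spacing = 1)
  spike$values[16, 16, 16] <- 1
  out <- apply_system_blur(spike, 6)
  expect_lt(abs(sum(out$values) - 1), 1e-6)
  prof <- out$values[, 16, 16]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation of the half-height crossings
  lo <- min(above); hi <- max(above)
  xl <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  xr <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_lt(abs((xr - xl) - 6), 0.5)
})

test_that("image mean over a deep background region approaches the background uptake", {
  spec <- phantom_spec(grid_shape = c(40, 40, 40), spacing = 2,
                       background_uptake = 2,
                       components = lesion_component("sphere", c(60, 60, 60),
                                                     8, 8),
                       blur_fwhm = 6, noise_sigma = 0.3, seed = 3)
  ph <- make_phantom(spec)
  roi <- ph$image$values[1:10, 1:10, 1:10]
  expect_lt(abs(mean(roi) - 2), 3 * 0.3 / sqrt(length(roi)))
})

test_that("SUV conversion follows the injected-activity normalization", {
  conc <- pet_volume(array(5e3, c(4, 4, 4)), spacing = 2, units = "raw")
  cal <- suv_calibration(injected_activity_bq = 185e6, body_weight_g = 70e3)
  suv <- to_suv(conc, cal)
  expect_equal(suv$values[1], 5e3 * 7e4 / 1.85e8)   # 1.8919...
  expect_equal(suv$units, "suv")
  # concentration equal to activity per unit weight gives SUV 1 everywhere
  conc1 <- pet_volume(array(185e6 / 70e3, c(3, 3, 3)), 2, "raw")
  expect_equal(max(abs(to_suv(conc1, cal)$values - 1)), 0)
  # doubling body weight doubles every SUV
  cal2 <- suv_calibration(185e6, 140e3)
  expect_equal(to_suv(conc, cal2)$values, 2 * suv$values)
  expect_error(suv_calibration(-1, 70e3), "injected_activity")
  expect_error(to_suv(suv, cal), "already")
})

test_that("phantom specs round-trip through YAML configs", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24), spacing = c(2, 2, 3),
                       background_uptake = 2,
                       components = heterogeneous_lesion(10, c(24, 24, 30)),
                       blur_fwhm = 6, noise_sigma = 0.3, seed = 17)
  path <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back$grid_shape, spec$grid_shape)
  expect_equal(back$spacing, spec$spacing)
  expect_equal(back$seed, spec$seed)            # seed is recorded
  a <- make_phantom(spec); b <- make_phantom(back)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$truth$values, b$truth$values)
})

test_that("cohorts are reproducible with volumes in the stated range", {
  a <- make_cohort(7, master_seed = 5)
  b <- make_cohort(7, master_seed = 5)
  vols <- vapply(a, function(cs) mask_volume_cm3(cs$truth), numeric(1))
  expect_length(a, 7)
  expect_true(all(vols >= 4 & vols <= 33))
  expect_identical(lapply(a, function(cs) cs$image$values),
                   lapply(b, function(cs) cs$image$values))
  expect_length(make_cohort(1, master_seed = 2), 1)
})
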