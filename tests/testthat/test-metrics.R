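test_that("the overlap index matches direct voxel counting on hand-built masks", {
  dims <- c(4, 4, 4)
  a <- pet_mask(array(FALSE, dims), 2); b <- pet_mask(array(FALSE, dims), 2)
  a$values[1:2, 1:2, 1:2] <- TRUE          # |A| = 8
  b$values[1:2, 1:2, 2:3] <- TRUE          # |B| = 8, |A & B| = 4
  expect_equal(spatial_overlap_index(a, b), 0.5)
  expect_equal(spatial_overlap_index(a, a), 1)
  disjoint <- pet_mask(array(FALSE, dims), 2)
  disjoint$values[4, 4, 4] <- TRUE
  expect_equal(spatial_overlap_index(a, disjoint), 0)
  empty <- pet_mask(array(FALSE, dims), 2)
  expect_equal(spatial_overlap_index(empty, empty), 1)
  expect_equal(spatial_overlap_index(a, empty), 0)
  expect_equal(spatial_overlap_index(a, b), spatial_overlap_index(b, a))
  expect_error(spatial_overlap_index(a, pet_mask(array(FALSE, c(3, 3, 3)), 2)),
               "shape")
})

test_that("classification error counts false voxels against the reference size", {
  dims <- c(10, 10, 1)
  ref <- pet_mask(array(FALSE, dims), 2); ref$values[1:10, 1:10, 1] <- TRUE
  seg <- ref
  expect_equal(classification_error(seg, ref)$ce_percent, 0)
  # PCE 10, NCE 5 against VoIL 100
  seg2 <- pet_mask(array(FALSE, c(20, 10, 1)), 2)
  ref2 <- pet_mask(array(FALSE, c(20, 10, 1)), 2)
  ref2$values[1:10, , 1] <- TRUE
  seg2$values[1:10, , 1] <- TRUE
  seg2$values[6:10, 1, 1] <- FALSE          # 5 missed
  seg2$values[11:20, 1, 1] <- TRUE          # 10 spurious
  ce <- classification_error(seg2, ref2)
  expect_equal(c(ce$pce, ce$nce, ce$voil), c(10, 5, 100))
  expect_equal(ce$ce_percent, 15)
  # a 2.5x over-covering superset puts CE above 100% (PCE 150, NCE 0)
  sup <- pet_mask(array(FALSE, c(25, 10, 1)), 2)
  sup$values[1:25, 1:10, 1] <- TRUE         # 250 voxels over a 100-voxel ref
  ref25 <- pet_mask(array(FALSE, c(25, 10, 1)), 2)
  ref25$values[1:10, , 1] <- TRUE
  ce2 <- classification_error(sup, ref25)
  expect_equal(ce2$ce_percent, 150)
  expect_error(classification_error(seg2, pet_mask(array(FALSE, c(20, 10, 1)), 2)),
               "empty")
  # CE is not symmetric: swapping roles changes the denominator
  half <- pet_mask(array(FALSE, c(20, 10, 1)), 2)
  half$values[1:5, , 1] <- TRUE
  expect_false(isTRUE(all.equal(
    classification_error(half, ref2)$ce_percent,
    classification_error(ref2, half)$ce_percent)))
})

test_that("relative volume error is signed and independent of voxel size", {
  dims <- c(10, 10, 1)
  ref <- pet_mask(array(FALSE, dims), 2); ref$values[1:10, 1:10, 1] <- TRUE
  seg <- pet_mask(array(FALSE, dims), 2); seg$values[1:10, 1:10, 1] <- TRUE
  seg$values[1:6, 1, 1] <- FALSE            # 94 voxels vs 100
  expect_equal(relative_volume_error(seg, ref), -6)
  expect_equal(relative_volume_error(ref, ref), 0)
  seg4 <- pet_mask(seg$values, 4); ref4 <- pet_mask(ref$values, 4)
  expect_equal(relative_volume_error(seg4, ref4), -6)
})

test_that("SOI and CE behave monotonically as the segmentation erodes", {
  dims <- c(12, 12, 12)
  ref <- pet_mask(array(FALSE, dims), 2)
  ref$values[3:10, 3:10, 3:10] <- TRUE
  sois <- ces <- numeric(0)
  for (shrink in 0:3) {
    seg <- pet_mask(array(FALSE, dims), 2)
    seg$values[(3 + shrink):(10 - shrink), 3:10, 3:10] <- TRUE
    sois <- c(sois, spatial_overlap_index(seg, ref))
    ces <- c(ces, classification_error(seg, ref)$ce_percent)
  }
  expect_true(all(diff(sois) < 0))
  expect_true(all(diff(ces) > 0))
})

test_that("the paired t-test matches the closed-form statistic and flags degeneracies", {
  d <- c(2, -1, 3, 0, 1, -2, 4)
  x <- 10 + d; y <- rep(10, 7)
  r <- paired_ttest(x, y)
  t_hand <- mean(d) / (sd(d) / sqrt(7))
  expect_lt(abs(r$t_statistic - t_hand), 1e-10)
  expect_equal(r$df, 6)
  ref <- t.test(x, y, paired = TRUE)
  expect_lt(abs(r$p_value - ref$p.value), 1e-12)
  same <- paired_ttest(1:5, 1:5)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  const <- paired_ttest(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(is.infinite(const$t_statistic) && const$degenerate)
})

test_that("cohort summaries reproduce spreadsheet arithmetic on a 3-case fixture", {
  rec <- data.frame(case = 1:3, method = "m",
                    soi = c(0.5, 0.7, 0.9),
                    ce_percent = c(30, 20, 10),
                    seg_volume_cm3 = c(9, 11, 16),
                    ref_volume_cm3 = c(10, 10, 15),
                    rel_vol_err_percent = c(-10, 10, 100 / 15))
  s <- summarize_cohort(rec)
  expect_equal(nrow(s), 1L)
  expect_equal(s$soi_mean, 0.7)
  expect_equal(s$soi_sd, sd(c(0.5, 0.7, 0.9)))
  expect_equal(s$soi_min, 0.5)
  expect_equal(s$ce_mean, 20)
  expect_equal(s$volume_mean_cm3, 12)
  expect_equal(s$p_value, t.test(c(9, 11, 16), c(10, 10, 15),
                                 paired = TRUE)$p.value)
  single <- summarize_cohort(rec[1, ])
  expect_equal(single$soi_sd, 0)
  two <- summarize_cohort(transform(rbind(rec, rec), method = rep(c("a", "b"),
                                                                  each = 3)))
  expect_equal(nrow(two), 2L)
})
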