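test_that("a single-class mixture degenerates to the sample mean", {
  set.seed(2)
  x <- rnorm(500, 3, 0.5)
  fit <- em_fit(x, K = 1)
  expect_equal(unname(fit$means), mean(x), tolerance = 1e-6)
  expect_true(all(fit$responsibilities == 1))
})

test_that("EM recovers well-separated mixture parameters with a monotone likelihood", {
  for (seed in c(1, 8)) {
    set.seed(seed)
    n <- 2e4
    z <- runif(n) < 0.3
    x <- ifelse(z, rnorm(n, 10, 1), rnorm(n, 0, 1))   # separation 10 sigma
    fit <- em_fit(x, K = 2)
    expect_true(all(diff(fit$log_likelihood) >= -1e-6))
    mu <- sort(fit$means)
    expect_lt(abs(mu[2] - 10) / 10, 0.02)
    expect_lt(abs(max(fit$mixing) - 0.7), 0.02)
    expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-9))
  }
})

test_that("EM agrees with an independent mixture fit on the same draws", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attachment
  set.seed(5)
  x <- c(rnorm(3000, 1, 0.4), rnorm(1500, 6, 0.8))
  fit <- em_fit(x, K = 2)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
})

test_that("EM segmentation is exact on a two-level image and permutation invariant", {
  img <- two_level_volume(level = 9, background = 1)
  m <- em_segment(img, c(7, 7, 7), K = 2)
  expect_identical(m$values, img$values == 9)
  # class order in the initialization must not matter
  f1 <- em_fit(img, K = 2, init = list(means = c(1, 9), sds = c(1, 1),
                                       mixing = c(0.5, 0.5)))
  f2 <- em_fit(img, K = 2, init = list(means = c(9, 1), sds = c(1, 1),
                                       mixing = c(0.5, 0.5)))
  expect_equal(sort(f1$means), sort(f2$means), tolerance = 1e-6)
})

test_that("EM masks a heterogeneous lesion between its rim and full extent", {
  ph <- hetero_case(noise = 0.15, seed = 3)
  pc <- prepared_case(ph)
  m <- em_segment(pc$pre, pc$seed_point, K = 3)
  spec <- ph$spec
  box <- petseg:::lesion_region_box(ph$truth, 32)
  rim_only <- petseg:::crop_values(
    petseg:::component_mask(spec$components[[1]], spec$grid_shape,
                            spec$spacing) &
      !petseg:::component_mask(spec$components[[2]], spec$grid_shape,
                               spec$spacing), box)
  v <- sum(m$values)
  expect_gte(v, 0.5 * sum(rim_only))
  expect_lte(v, 1.3 * sum(pc$truth$values))
})

test_that("fuzzy memberships respect symmetry, exact hits and the simplex", {
  x <- matrix(c(0, 10, 5, 0.3), ncol = 1)   # two centroids at 0 and 10
  d2 <- petseg:::fcm_distances(x, matrix(c(0, 10), 2, 1), matrix(1, 2, 1))
  u <- petseg:::fcm_memberships(d2, b = 2)
  expect_equal(u[3, ], c(0.5, 0.5))          # equidistant voxel
  expect_equal(u[1, ], c(1, 0))              # voxel on a centroid
  expect_true(all(abs(rowSums(u) - 1) < 1e-12))
})

test_that("two-cluster FCM finds the level centroids with a nonincreasing objective", {
  x <- c(0, 0, 0, 10, 10, 10)
  fit <- fcm_fit(x, K = 2, b = 2, tol = 1e-8)
  expect_equal(sort(fit$centroids[, 1]), c(0, 10), tolerance = 1e-3)
  expect_true(all(diff(fit$objective) <= 1e-9))
})

test_that("FCM agrees with an independent fuzzy clustering implementation", {
  skip_if_not_installed("e1071")
  set.seed(3)
  x <- c(rnorm(300, 0, 0.3), rnorm(200, 5, 0.4))
  fit <- fcm_fit(x, K = 2, b = 2, tol = 1e-8)
  ref <- e1071::cmeans(matrix(x), centers = matrix(c(0, 5)), m = 2,
                       iter.max = 200)
  expect_equal(sort(fit$centroids[, 1]), sort(as.numeric(ref$centers)),
               tolerance = 1e-3)
})

test_that("FCM is invariant to feature-order permutation up to relabelling", {
  set.seed(6)
  x <- cbind(c(rnorm(80, 0), rnorm(80, 6)), c(rnorm(80, 2), rnorm(80, -1)))
  f1 <- fcm_fit(x, K = 2, tol = 1e-8)
  f2 <- fcm_fit(x[, 2:1], K = 2, tol = 1e-8)
  # same clusters, channels swapped (order by first fit's channel-1)
  o1 <- order(f1$centroids[, 1]); o2 <- order(f2$centroids[, 2])
  expect_equal(f1$centroids[o1, 1], f2$centroids[o2, 2], tolerance = 1e-4)
  expect_equal(f1$centroids[o1, 2], f2$centroids[o2, 1], tolerance = 1e-4)
})

test_that("cluster merging fuses the nearest pair and conserves memberships", {
  x <- c(rep(0, 10), rep(0.1, 10), rep(10, 10))
  fit <- fcm_fit(x, K = 3, tol = 1e-8)
  merged <- fcm_merge(fit, x, 2)
  expect_equal(nrow(merged$centroids), 2L)
  expect_true(all(abs(rowSums(merged$memberships) - 1) < 1e-9))
  # the two near-zero clusters merged, leaving ~{0.05, 10}
  expect_equal(sort(merged$centroids[, 1]), c(0.05, 10), tolerance = 0.05)
  # merging to the current K is the identity
  same <- fcm_merge(fit, x, 3)
  expect_identical(same$centroids, fit$centroids)
  expect_error(fcm_merge(fit, x, 4), "fewer")
})

test_that("defuzzification takes the maximum membership with ties to the hotter class", {
  st <- structure(list(memberships = rbind(c(0.9, 0.1), c(0.5, 0.5)),
                       centroids = matrix(c(1, 5), 2, 1), b = 2),
                  class = "fcm_state")
  lab <- defuzzify(st)
  expect_identical(lab, c(1L, 2L))           # tie goes to centroid 5
  expect_identical(dim(defuzzify(st, dims = c(2, 1, 1))), c(2L, 1L, 1L))
})

test_that("anisotropic diffusion conserves intensity and preserves edges better than Gaussian blur", {
  img <- pet_volume(array(4, c(8, 8, 8)), 2)
  expect_equal(anisotropic_diffusion(img, 5)$values, img$values,
               tolerance = 1e-12)
  set.seed(12)
  v <- array(1, c(24, 14, 14)); v[13:24, , ] <- 9
  noisy <- pet_volume(v + array(rnorm(length(v), 0, 0.3), dim(v)), 2)
  ad <- anisotropic_diffusion(noisy, iterations = 10, kappa = 1)
  expect_lt(abs(sum(ad$values) - sum(noisy$values)) / sum(noisy$values),
            0.001)
  # match the background-noise reduction with a Gaussian and compare edges
  roi_sd <- function(x) sd(x[2:9, 3:12, 3:12])
  fw <- 2
  repeat {
    gs <- gaussian_smooth(noisy, fw)
    if (roi_sd(gs$values) <= roi_sd(ad$values) || fw > 20) break
    fw <- fw + 1
  }
  step_height <- function(x) mean(x[16:22, 4:11, 4:11]) - mean(x[3:9, 4:11, 4:11])
  edge_width <- function(x) {
    prof <- apply(x[, 4:11, 4:11], 1, mean)
    h <- step_height(x)
    sum(prof > min(prof) + 0.1 * h & prof < min(prof) + 0.9 * h)
  }
  expect_lte(edge_width(ad$values), edge_width(gs$values))
})

test_that("the a-trous transform reconstructs exactly and localizes a spike at scale 1", {
  set.seed(9)
  img <- pet_volume(array(runif(18^3), c(18, 18, 18)), 2)
  tr <- atrous_transform(img, scales = 3)
  recon <- tr$residual + Reduce(`+`, tr$details)
  expect_lt(max(abs(recon - img$values)), 1e-10)
  const <- pet_volume(array(2, c(18, 18, 18)), 2)
  trc <- atrous_transform(const, scales = 2)
  expect_true(all(vapply(trc$details, function(d) max(abs(d)), 0) < 1e-12))
  spike <- pet_volume(array(0, c(18, 18, 18)), 2)
  spike$values[9, 9, 9] <- 1
  trs <- atrous_transform(spike, scales = 3)
  energy <- vapply(trs$details, function(d) sum(d^2), 0)
  expect_equal(which.max(energy), 1L)
  expect_error(atrous_transform(pet_volume(array(0, c(4, 4, 4)), 2), 4),
               "scale")
})

test_that("the wavelet variant reduces bit-exactly to plain FCM at zero regularization", {
  ph <- hetero_case(noise = 0.2, grid = 48, seed = 4)
  pc <- prepared_case(ph)
  plain <- segment_fcm(pc$pre, pc$seed_point)
  reduced <- segment_fcm_sw(pc$pre, pc$seed_point,
                            fcm_sw_params(beta0 = 0, use_diffusion = FALSE))
  expect_identical(plain$values, reduced$values)
})

test_that("the wavelet variant recovers the low-avidity core that plain FCM misses", {
  cover <- function(mask, core) sum(mask$values & core) / sum(core)
  fcm_cov <- fcmsw_cov <- numeric(0)
  for (seed in 1:3) {
    ph <- hetero_case(volume_cm3 = 18, noise = 0.3, seed = seed)
    pc <- prepared_case(ph)
    spec <- ph$spec
    box <- petseg:::lesion_region_box(ph$truth, 32)
    core <- petseg:::crop_values(
      petseg:::component_mask(spec$components[[2]], spec$grid_shape,
                              spec$spacing), box)
    fcm_cov <- c(fcm_cov, cover(segment_fcm(pc$pre, pc$seed_point), core))
    fcmsw_cov <- c(fcmsw_cov,
                   cover(segment_fcm_sw(pc$pre, pc$seed_point), core))
  }
  expect_gte(mean(fcmsw_cov), 0.9)
  expect_lt(mean(fcm_cov), 0.9)
})
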