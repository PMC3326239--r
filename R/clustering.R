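#' Fit a Gaussian mixture to voxel intensities by EM
#'
#' Maximum-likelihood estimation of a K-class univariate Gaussian mixture:
#' the E step computes per-voxel responsibilities
#' `p_ik = pi_k f_k(x_i) / sum_m pi_m f_m(x_i)` and the M step re-estimates
#' the mixing weights, means and standard deviations from the weighted
#' voxels. Means are initialized at intensity quantiles, which makes the
#' fit deterministic.
#'
#' @param x A [pet_volume()] or numeric vector of intensities.
#' @param K Number of classes (>= 1).
#' @param init Optional list with `means`, `sds`, `mixing` overriding the
#'   quantile initialization.
#' @param tol Stop when the log-likelihood gain drops below this.
#' @param max_iter Iteration cap.
#' @return An object of class `pet_gmm`: `K`, `mixing`, `means`, `sds`,
#'   `responsibilities` (N x K), `log_likelihood` (per-iteration trace),
#'   `converged`, `reseeded` (collapse-recovery flag).
#' @export
em_fit <- function(x, K = 3, init = NULL, tol = 1e-6, max_iter = 200) {
  if (inherits(x, "pet_volume")) x <- as.numeric(x$values)
  x <- as.numeric(x)
  stopifnot(K >= 1, length(unique(x)) >= K)
  n <- length(x)
  if (is.null(init)) {
    # deterministic means spread over the intensity range: quantile-based
    # starts collapse when one class (the background) dominates the
    # histogram, which is the norm for lesion-centred PET volumes
    rng <- range(x)
    means <- rng[1] + (seq_len(K) - 0.5) / K * diff(rng)
    sds <- rep(max(stats::sd(x) / K, 1e-8), K)
    mixing <- rep(1 / K, K)
  } else {
    means <- init$means; sds <- init$sds; mixing <- init$mixing
  }
  # variance floor at 0.5% of the intensity range: prevents the classic
  # likelihood degeneracy where a class collapses onto a zero-variance
  # intensity spike (flat background) and the remaining classes cascade
  sd_floor <- max(1e-8, 5e-3 * diff(range(x)))
  ll_trace <- numeric(0)
  reseeded <- FALSE
  converged <- FALSE
  resp <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k)
      log(mixing[k]) + stats::dnorm(x, means[k], sds[k], log = TRUE),
      numeric(n))
    m <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
    w <- exp(logd - m)
    rs <- rowSums(w)
    resp <- w / rs
    ll <- sum(m + log(rs))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && ll - ll_trace[it - 1] < tol) { converged <- TRUE; break }
    nk <- colSums(resp)
    mixing <- nk / n
    means <- colSums(resp * x) / nk
    sds <- sqrt(colSums(resp * (outer(x, means, `-`))^2) / nk)
    if (any(!is.finite(sds))) {
      # collapsing component (no support): re-seed with jitter and flag it
      bad <- which(!is.finite(sds))
      sds[bad] <- max(stats::sd(x) / K, sd_floor)
      means[bad] <- means[bad] + (seq_along(bad)) * 1e-3 * stats::sd(x)
      reseeded <- TRUE
    }
    sds <- pmax(sds, sd_floor)
  }
  structure(list(K = K, mixing = mixing, means = means, sds = sds,
                 responsibilities = resp, log_likelihood = ll_trace,
                 converged = converged, reseeded = reseeded),
            class = "pet_gmm")
}

#' @export
print.pet_gmm <- function(x, ...) {
  cat(sprintf("<pet_gmm> K = %d, logLik = %.4f (%d EM iterations)\n",
              x$K, utils::tail(x$log_likelihood, 1), length(x$log_likelihood)))
  print(data.frame(mixing = x$mixing, mean = x$means, sd = x$sds))
  invisible(x)
}

#' Gaussian-mixture (EM) segmentation
#'
#' Fits a K-class mixture to the image intensities; the tumour is the set
#' of voxels whose maximum-responsibility class is the highest-mean class,
#' restricted to the 26-connected component at the seed. Invariant to class
#' relabelling.
#'
#' @param img A [pet_volume()] (typically preprocessed).
#' @param seed_point Length-3 voxel index inside the lesion.
#' @param K Number of intensity classes (default 3: background /
#'   transition / tumour).
#' @param ... Passed on to [em_fit()].
#' @return A [pet_mask()].
#' @export
em_segment <- function(img, seed_point, K = 3, ...) {
  stopifnot(inherits(img, "pet_volume"))
  fit <- em_fit(img, K = K, ...)
  labels <- max.col(fit$responsibilities, ties.method = "last")
  tumour_class <- which.max(fit$means)
  mask <- array(labels == tumour_class, dim(img$values))
  if (!any(mask)) stop("highest-mean class is empty", call. = FALSE)
  keep_seed_component(pet_mask(mask, img$spacing), seed_point)
}

keep_seed_component <- function(mask, seed_point) {
  dims <- dim(mask$values)
  seed_point <- seed_index(seed_point, dims)
  if (!any(mask$values)) return(mask)
  if (!mask$values[seed_point[1], seed_point[2], seed_point[3]]) {
    idx <- which(mask$values)
    sub <- arrayInd(idx, dims)
    d2 <- colSums((t(sub) - seed_point)^2 * mask$spacing^2)
    seed_point <- sub[which.min(d2), ]
  }
  seed0 <- (seed_point[1] - 1L) +
    dims[1] * ((seed_point[2] - 1L) + dims[2] * (seed_point[3] - 1L))
  comp <- cpp_seed_component(as.logical(mask$values), dims, as.integer(seed0))
  pet_mask(array(comp, dims), mask$spacing)
}

# Squared distances (N x K) under per-class channel weights (K x C).
fcm_distances <- function(x, centroids, channel_weights) {
  K <- nrow(centroids)
  d2 <- matrix(0, nrow(x), K)
  for (k in seq_len(K)) {
    acc <- 0
    for (ch in seq_len(ncol(x))) {
      w <- channel_weights[k, ch]
      if (w != 0) acc <- acc + w * (x[, ch] - centroids[k, ch])^2
    }
    d2[, k] <- acc
  }
  d2
}

fcm_memberships <- function(d2, b) {
  # u_ik = d_ik^(-2/(b-1)) / sum_k d_ik^(-2/(b-1)); exact hits get
  # membership 1 in their class
  p <- 1 / (b - 1)
  hit <- d2 < 1e-24
  inv <- if (p == 1) 1 / pmax(d2, 1e-300) else (pmax(d2, 1e-300))^(-p)
  u <- inv / rowSums(inv)
  hit_rows <- which(rowSums(hit) > 0)
  if (length(hit_rows)) {
    u[hit_rows, ] <- 0
    u[cbind(hit_rows, max.col(-d2[hit_rows, , drop = FALSE]))] <- 1
  }
  u
}

#' Fuzzy c-means clustering of voxel features
#'
#' Alternates the inverse-squared-distance membership update and the
#' `u^b`-weighted centroid update until the largest centroid shift falls
#' below `tol`. Centroids are initialized at quantiles of the first feature
#' channel, so the fit is deterministic. An optional K x C matrix of
#' per-class channel weights generalizes the distance to
#' `d_ik^2 = sum_c w_kc (x_ic - c_kc)^2` (used by the spatially
#' regularized variant); with unit weights this is the classic algorithm.
#'
#' @param features Numeric matrix (voxels x channels) or vector.
#' @param K Number of clusters (>= 2).
#' @param b Fuzzifier exponent > 1 (default 2).
#' @param tol Convergence tolerance on the centroid shift.
#' @param max_iter Iteration cap.
#' @param centroids Optional K x C initial centroids.
#' @param channel_weights Optional K x C nonnegative weights.
#' @return An object of class `fcm_state`: `memberships` (N x K),
#'   `centroids` (K x C), `b`, `objective` (per-iteration trace),
#'   `iterations`, `converged`, `channel_weights`, `reseeded`.
#' @export
fcm_fit <- function(features, K, b = 2, tol = 1e-4, max_iter = 100,
                    centroids = NULL, channel_weights = NULL) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  stopifnot(K >= 2, b > 1, nrow(x) >= K)
  C <- ncol(x)
  if (is.null(channel_weights)) channel_weights <- matrix(1, K, C)
  stopifnot(identical(dim(channel_weights), c(as.integer(K), C)),
            all(channel_weights >= 0))
  if (is.null(centroids)) {
    ord <- order(x[, 1])
    pick <- ord[ceiling((seq_len(K) - 0.5) / K * nrow(x))]
    centroids <- x[pick, , drop = FALSE]
  }
  centroids <- matrix(as.double(as.matrix(centroids)), K, C)
  wmat <- matrix(as.double(channel_weights), K, C)
  fit <- cpp_fcm_fit(x, centroids, wmat, b, tol, as.integer(max_iter))
  centroids <- fit$centroids
  d2 <- fcm_distances(x, centroids, wmat)
  u <- fcm_memberships(d2, b)
  obj <- c(fit$objective, sum(u^b * d2))
  structure(list(memberships = u, centroids = centroids, b = b,
                 objective = obj, iterations = fit$iterations,
                 converged = fit$converged,
                 channel_weights = wmat, reseeded = fit$reseeded),
            class = "fcm_state")
}

#' @export
print.fcm_state <- function(x, ...) {
  cat(sprintf("<fcm_state> K = %d, b = %g, objective = %.6g (%d iterations%s)\n",
              nrow(x$centroids), x$b, utils::tail(x$objective, 1),
              x$iterations, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Merge an over-clustered FCM state down to a target class count
#'
#' Starting from an oversized cluster count avoids misidentifying
#' conflicting regions; the merge step then repeatedly fuses the pair of
#' clusters with the smallest centroid distance (memberships summed,
#' centroid recomputed as the `u^b`-weighted mean of the data) until
#' `K_target` classes remain. Centroid distances are measured in the full
#' feature space with the pair-averaged channel weights.
#'
#' @param state An `fcm_state` from [fcm_fit()].
#' @param features The data the state was fitted on.
#' @param K_target Desired number of clusters (>= 2).
#' @return The merged `fcm_state`.
#' @export
fcm_merge <- function(state, features, K_target) {
  stopifnot(inherits(state, "fcm_state"), K_target >= 2)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  u <- state$memberships
  cen <- state$centroids
  w <- state$channel_weights
  b <- state$b
  if (nrow(cen) < K_target)
    stop("state has fewer clusters than `K_target`", call. = FALSE)
  while (nrow(cen) > K_target) {
    K <- nrow(cen)
    best <- c(NA, NA); best_d <- Inf
    for (k in seq_len(K - 1)) for (l in (k + 1):K) {
      wp <- (w[k, ] + w[l, ]) / 2
      d <- sum(wp * (cen[k, ] - cen[l, ])^2)
      if (d < best_d) { best_d <- d; best <- c(k, l) }
    }
    k <- best[1]; l <- best[2]
    u[, k] <- u[, k] + u[, l]
    ubk <- u[, k]^b
    cen[k, ] <- colSums(ubk * x) / sum(ubk)
    w[k, ] <- (w[k, ] + w[l, ]) / 2
    u <- u[, -l, drop = FALSE]
    cen <- cen[-l, , drop = FALSE]
    w <- w[-l, , drop = FALSE]
  }
  state$memberships <- u
  state$centroids <- cen
  state$channel_weights <- w
  d2 <- fcm_distances(x, cen, w)
  state$objective <- c(state$objective, sum(u^b * d2))
  state
}

#' Defuzzify an FCM state to a label grid
#'
#' Per-voxel argmax over memberships; ties are broken towards the class
#' with the higher first-channel centroid.
#'
#' @param state An `fcm_state`.
#' @param dims Optional array dimensions for the returned labels.
#' @return An integer vector (or array when `dims` is given) of class
#'   labels in `1:K`.
#' @export
defuzzify <- function(state, dims = NULL) {
  stopifnot(inherits(state, "fcm_state"))
  ord <- order(state$centroids[, 1])        # columns by ascending centroid
  u_sorted <- state$memberships[, ord, drop = FALSE]
  labels_sorted <- max.col(u_sorted, ties.method = "last")
  labels <- ord[labels_sorted]
  if (!is.null(dims)) labels <- array(labels, dims)
  labels
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing by the explicit diffusion scheme with
#' conductance `exp(-(|grad I| / kappa)^2)` on the 6-neighbourhood and the
#' stable step `1/(2 * ndim) = 1/6`. Zero-flux boundaries conserve total
#' intensity.
#'
#' @param img A [pet_volume()].
#' @param iterations Number of diffusion steps (default 10).
#' @param kappa Conductance scale in image units; `NULL` uses 10% of the
#'   robust (1st-99th percentile) intensity range.
#' @return The diffused [pet_volume()].
#' @export
anisotropic_diffusion <- function(img, iterations = 10, kappa = NULL) {
  stopifnot(inherits(img, "pet_volume"), iterations >= 1)
  if (is.null(kappa)) kappa <- 0.1 * robust_range(img$values)
  out <- cpp_aniso_diffusion(as.numeric(img$values), dim(img$values),
                             as.integer(iterations), kappa, 1 / 6)
  pet_volume(array(out, dim(img$values)), img$spacing, img$units)
}

#' Undecimated a-trous wavelet transform
#'
#' Separable B3-spline smoothing (kernel (1,4,6,4,1)/16) with tap spacing
#' `2^(j-1)` at scale j; `detail_j = smooth_(j-1) - smooth_j`. The
#' decomposition reconstructs exactly:
#' `image = residual + sum_j detail_j`.
#'
#' @param img A [pet_volume()].
#' @param scales Number of detail scales (>= 1).
#' @return A list with `details` (list of 3-D arrays, fine to coarse),
#'   `residual` (coarse approximation) and `scales`.
#' @export
atrous_transform <- function(img, scales = 3) {
  stopifnot(inherits(img, "pet_volume"), scales >= 1)
  dims <- dim(img$values)
  if (2^(scales - 1) * 2 >= min(dims))
    stop("scale too large for grid", call. = FALSE)
  smooth <- as.numeric(img$values)
  details <- vector("list", scales)
  for (j in seq_len(scales)) {
    nxt <- cpp_atrous_smooth(smooth, dims, as.integer(2^(j - 1)))
    details[[j]] <- array(smooth - nxt, dims)
    smooth <- as.numeric(nxt)
  }
  list(details = details, residual = array(smooth, dims), scales = scales)
}

# Coarse-scale (wavelet-denoised) image: residual plus all detail planes
# above the scale floor, i.e. the B3 approximation at `floor` scales.
wavelet_denoised <- function(img, scales = 3, floor = 2) {
  stopifnot(floor <= scales)
  tr <- atrous_transform(img, scales)
  out <- tr$residual
  if (floor < scales)
    for (j in (floor + 1):scales) out <- out + tr$details[[j]]
  pet_volume(out, img$spacing, img$units)
}

#' Parameters of the spatially regularized FCM variant
#'
#' @param K_init Oversized initial cluster count (default 9).
#' @param K_target Final cluster count after merging (default 3: tumour /
#'   transition / background).
#' @param b Fuzzifier (default 2).
#' @param wavelet_scales Depth of the a-trous decomposition (default 3).
#' @param scale_floor Detail scales treated as noise and removed from the
#'   wavelet channel (default 2).
#' @param beta0 Overall strength of the wavelet regularization (default
#'   0.8); 0 disables all spatial regularization, reducing the method to
#'   plain FCM.
#' @param gamma Exponent shaping how the per-class weights
#'   `beta_k = beta0 * ((c_k - c_min)/(c_max - c_min))^gamma` concentrate on
#'   high-uptake classes (default 2).
#' @param diffusion_iters,diffusion_kappa Anisotropic-diffusion settings
#'   for the edge-preserved side channel.
#' @param use_diffusion Include the diffusion-filtered channel (default
#'   TRUE).
#' @param fill_cavities Fill enclosed non-tumour cavities in the final mask
#'   (default TRUE); only applied when `beta0 > 0`, as part of the spatial
#'   regularization.
#' @return An object of class `fcm_sw_params`.
#' @export
fcm_sw_params <- function(K_init = 9, K_target = 3, b = 2, wavelet_scales = 3,
                          scale_floor = 2, beta0 = 0.8, gamma = 2,
                          diffusion_iters = 10, diffusion_kappa = NULL,
                          use_diffusion = TRUE, fill_cavities = TRUE) {
  stopifnot(K_init >= K_target, K_target >= 2, b > 1, beta0 >= 0,
            wavelet_scales >= 1, scale_floor <= wavelet_scales)
  structure(list(K_init = as.integer(K_init), K_target = as.integer(K_target),
                 b = b, wavelet_scales = as.integer(wavelet_scales),
                 scale_floor = as.integer(scale_floor), beta0 = beta0,
                 gamma = gamma, diffusion_iters = as.integer(diffusion_iters),
                 diffusion_kappa = diffusion_kappa,
                 use_diffusion = isTRUE(use_diffusion),
                 fill_cavities = isTRUE(fill_cavities)),
            class = "fcm_sw_params")
}

standardize_channel <- function(v) {
  s <- stats::sd(v)
  if (s < 1e-12) s <- 1
  (v - mean(v)) / s
}

# Shared clustering engine: over-clustered (optionally weighted) FCM fit,
# merge to K_target, defuzzify, keep the highest-centroid class at the
# seed.
fcm_segment_engine <- function(img, seed_point, features, K_init, K_target,
                               b, beta0, gamma, wavelet_channel = NULL,
                               fill = FALSE) {
  dims <- dim(img$values)
  x <- do.call(cbind, lapply(features, standardize_channel))
  if (!is.null(wavelet_channel))
    x <- cbind(x, standardize_channel(wavelet_channel))
  # segmentation-grade tolerance: channels are standardized, so 1e-3 is
  # well below a voxel's influence on the defuzzified boundary
  fit <- fcm_fit(x, K = K_init, b = b, tol = 1e-3)
  if (!is.null(wavelet_channel) && beta0 > 0) {
    # per-class wavelet weights from the plain fit's intensity centroids:
    # beta_k = beta0 * ((c_k - min)/(max - min))^gamma, so the wavelet
    # channel carries most weight (1 + beta_k) in high-uptake classes
    c1 <- fit$centroids[, 1]
    pos <- (c1 - min(c1)) / max(diff(range(c1)), 1e-12)
    beta_k <- beta0 * pos^gamma
    w <- matrix(1, K_init, ncol(x))
    w[, ncol(x)] <- 1 + beta_k
    fit <- fcm_fit(x, K = K_init, b = b, tol = 1e-3,
                   centroids = fit$centroids, channel_weights = w)
  }
  merged <- fcm_merge(fit, x, K_target)
  labels <- defuzzify(merged, dims)
  # tumour classes: centroid (intensity channel) closer to the hottest
  # class than to the background class; robust to merges that split the
  # lesion across two classes instead of isolating the transition shell
  c1 <- merged$centroids[, 1]
  tumour_classes <- which(abs(c1 - max(c1)) < abs(c1 - min(c1)))
  mask <- pet_mask(array(labels %in% tumour_classes, dims), img$spacing)
  mask <- keep_seed_component(mask, seed_point)
  if (fill && any(mask$values))
    mask <- pet_mask(array(cpp_fill_holes(as.logical(mask$values), dims), dims),
                     img$spacing)
  mask
}

#' Fuzzy c-means segmentation
#'
#' Intensity-only FCM with the over-clustering/merging strategy: fit
#' `K_init` clusters, merge nearest centroids down to `K_target`, defuzzify
#' by maximum membership, and keep the seed's connected component of the
#' highest-centroid class.
#'
#' @param img A [pet_volume()] (typically preprocessed).
#' @param seed_point Length-3 voxel index inside the lesion.
#' @param K_init,K_target Over-clustered and final class counts
#'   (defaults 9 and 3).
#' @param b Fuzzifier (default 2).
#' @return A [pet_mask()].
#' @export
segment_fcm <- function(img, seed_point, K_init = 9, K_target = 3, b = 2) {
  stopifnot(inherits(img, "pet_volume"))
  fcm_segment_engine(img, seed_point,
                     features = list(as.numeric(img$values)),
                     K_init = K_init, K_target = K_target, b = b,
                     beta0 = 0, gamma = 1)
}

#' Spatially regularized FCM segmentation (wavelet variant)
#'
#' Extends [segment_fcm()] with spatial context for heterogeneous lesions.
#' Three voxel channels are clustered: the (preprocessed) intensity, an
#' anisotropic-diffusion-filtered copy (edge-preserved local context), and
#' the coarse a-trous wavelet approximation (multiscale context in which a
#' heterogeneous lesion appears as a single high-uptake blob). The wavelet
#' channel enters the objective with per-class weights
#' `beta_k = beta0 * ((c_k - c_min)/(c_max - c_min))^gamma`, so its
#' influence is strongest for high-uptake classes; cluster merging acts in
#' the full feature space, letting low-avidity lesion regions that share
#' the lesion's coarse-scale context merge with the tumour class. Enclosed
#' non-tumour cavities (necrotic-like cores surrounded by the delineated
#' rim) are filled as the final spatial-regularization step. With
#' `beta0 = 0` every regularization weight vanishes and the method reduces
#' exactly to plain FCM on the supplied intensity channel.
#'
#' @param img A [pet_volume()] (typically preprocessed).
#' @param seed_point Length-3 voxel index inside the lesion.
#' @param params An [fcm_sw_params()].
#' @return A [pet_mask()].
#' @export
segment_fcm_sw <- function(img, seed_point, params = fcm_sw_params()) {
  stopifnot(inherits(img, "pet_volume"), inherits(params, "fcm_sw_params"))
  features <- list(as.numeric(img$values))
  if (params$use_diffusion && params$beta0 > 0)
    features <- c(features, list(as.numeric(
      anisotropic_diffusion(img, params$diffusion_iters,
                            params$diffusion_kappa)$values)))
  wavelet_channel <- NULL
  if (params$beta0 > 0)
    wavelet_channel <- as.numeric(
      wavelet_denoised(img, params$wavelet_scales, params$scale_floor)$values)
  fcm_segment_engine(img, seed_point, features,
                     K_init = params$K_init, K_target = params$K_target,
                     b = params$b, beta0 = params$beta0, gamma = params$gamma,
                     wavelet_channel = wavelet_channel,
                     fill = params$fill_cavities && params$beta0 > 0)
}
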