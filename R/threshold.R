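#' Published adaptive-threshold formulas
#'
#' The four published rules behind the adaptive thresholding segmenters,
#' exposed directly so they can be evaluated on known statistics:
#' * `threshold_biehl_pct()` — volume-adaptive percentage of SUVmax:
#'   `%T = intercept - slope * log10(volume in cm^3)` (defaults 59.1, 18.5).
#' * `threshold_black()` — signal-adaptive SUV threshold:
#'   `T = gain * mean target SUV + offset` (defaults 0.307, 0.588).
#' * `threshold_nestle()` — background-corrected threshold:
#'   `T = beta * I_mean + I_bkg` with `beta = 0.15`, `I_mean` the mean
#'   intensity inside the 70% isocontour.
#' * `threshold_schaefer_fraction()` — contrast-oriented fraction of SUVmax:
#'   `(a * SUVmean70 + b * BKG) / SUVmax` with size-dependent coefficients
#'   (a = b = 0.50 for sphere diameter >= 3 cm; a = 0.67, b = 0.60 below).
#'
#' @param volume_cm3 Lesion volume in cm^3.
#' @param intercept,slope Percentage intercept and slope per decade of
#'   volume (slope > 0).
#' @param mean_target_suv Mean SUV over the target region.
#' @param gain,offset Linear coefficients of the signal-adaptive rule.
#' @param i_mean Mean intensity inside the 70% isocontour.
#' @param i_bkg Mean background intensity.
#' @param beta Weight on `i_mean` (default 0.15).
#' @param suv_mean70 Mean SUV of the 70% isocontour.
#' @param bkg Mean background SUV.
#' @param suv_max Maximum SUV of the lesion.
#' @param size `"large"` (diameter >= 3 cm) or `"small"`.
#' @param a_large,b_large,a_small,b_small Scanner-dependent coefficients.
#' @return A threshold: percent of SUVmax (`threshold_biehl_pct`), SUV
#'   (`threshold_black`), intensity (`threshold_nestle`), or a fraction of
#'   SUVmax (`threshold_schaefer_fraction`).
#' @name threshold_formulas
NULL

#' @rdname threshold_formulas
#' @export
threshold_biehl_pct <- function(volume_cm3, intercept = 59.1, slope = 18.5) {
  stopifnot(slope > 0, volume_cm3 > 0)
  intercept - slope * log10(volume_cm3)
}

#' @rdname threshold_formulas
#' @export
threshold_black <- function(mean_target_suv, gain = 0.307, offset = 0.588) {
  stopifnot(gain > 0)
  gain * mean_target_suv + offset
}

#' @rdname threshold_formulas
#' @export
threshold_nestle <- function(i_mean, i_bkg, beta = 0.15) {
  beta * i_mean + i_bkg
}

#' @rdname threshold_formulas
#' @export
threshold_schaefer_fraction <- function(suv_mean70, bkg, suv_max,
                                        size = c("large", "small"),
                                        a_large = 0.50, b_large = 0.50,
                                        a_small = 0.67, b_small = 0.60) {
  size <- match.arg(size)
  stopifnot(suv_max > 0, all(c(a_large, b_large, a_small, b_small) > 0))
  if (size == "large") (a_large * suv_mean70 + b_large * bkg) / suv_max
  else (a_small * suv_mean70 + b_small * bkg) / suv_max
}

threshold_result <- function(mask, threshold, iterations = 1L,
                             converged = TRUE) {
  structure(list(mask = mask, threshold = threshold,
                 iterations = as.integer(iterations),
                 converged = converged,
                 empty = !any(mask$values)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> T = %.4g, %d voxels (%.2f cm^3), %s after %d iteration(s)\n",
              x$threshold, sum(x$mask$values), mask_volume_cm3(x$mask),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

seed_index <- function(seed_point, dims) {
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L || any(seed_point < 1L) ||
      any(seed_point > dims))
    stop("`seed_point` must be a voxel index inside the image", call. = FALSE)
  seed_point
}

#' Hottest voxel of an image
#'
#' @param img A [pet_volume()].
#' @param within Optional [pet_mask()] restricting the search.
#' @return Length-3 voxel index of the maximum intensity.
#' @export
hottest_voxel <- function(img, within = NULL) {
  v <- img$values
  if (!is.null(within)) {
    v <- ifelse(within$values, v, -Inf)
  }
  arrayInd(which.max(v), dim(img$values))[1, ]
}

#' Threshold an image and keep the seed's connected component
#'
#' Selects the voxels at or above `threshold` and restricts them to the
#' 26-connected component containing `seed_point` (or, when the seed itself
#' is below threshold, the component of the nearest supra-threshold voxel).
#' If no voxel reaches the threshold an empty mask is returned (a distinct
#' signal, not an error).
#'
#' @param img A [pet_volume()].
#' @param threshold Threshold in image units.
#' @param seed_point Length-3 voxel index.
#' @return A [pet_mask()]; all-`FALSE` when nothing is supra-threshold.
#' @export
mask_from_threshold <- function(img, threshold, seed_point) {
  dims <- dim(img$values)
  seed_point <- seed_index(seed_point, dims)
  supra <- img$values >= threshold
  empty <- pet_mask(array(FALSE, dims), img$spacing)
  if (!any(supra)) return(empty)
  seed0 <- (seed_point[1] - 1L) +
    dims[1] * ((seed_point[2] - 1L) + dims[2] * (seed_point[3] - 1L))
  if (!supra[seed_point[1], seed_point[2], seed_point[3]]) {
    # jump to the nearest supra-threshold voxel (mm distance)
    idx <- which(supra)
    sub <- arrayInd(idx, dims)
    d2 <- colSums((t(sub) - seed_point)^2 * img$spacing^2)
    near <- sub[which.min(d2), ]
    seed0 <- (near[1] - 1L) + dims[1] * ((near[2] - 1L) + dims[2] * (near[3] - 1L))
  }
  comp <- cpp_seed_component(as.logical(supra), dims, as.integer(seed0))
  pet_mask(array(comp, dims), img$spacing)
}

region_max <- function(img, region = NULL) {
  if (is.null(region)) max(img$values)
  else max(img$values[region$values])
}

# Mean intensity inside the iso_fraction * Imax isocontour of the lesion
# component at the seed.
isocontour_mean <- function(img, seed_point, iso_fraction, region = NULL) {
  imax <- region_max(img, region)
  m <- mask_from_threshold(img, iso_fraction * imax, seed_point)
  if (!any(m$values)) stop("empty isocontour", call. = FALSE)
  mean(img$values[m$values])
}

#' Fixed percentage-of-SUVmax segmentation
#'
#' Thresholds at `fraction` of the maximum intensity of the search region
#' (default 40%) and keeps the seed's connected component.
#'
#' @param img A [pet_volume()].
#' @param seed_point Length-3 voxel index inside/near the lesion.
#' @param fraction Fraction of SUVmax in (0, 1), default 0.40.
#' @param region Optional [pet_mask()] search region for SUVmax.
#' @return A `threshold_result`.
#' @export
segment_pct_max <- function(img, seed_point, fraction = 0.40, region = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (max(img$values) - min(img$values) <= .Machine$double.eps)
    stop("degenerate input: image is flat", call. = FALSE)
  T <- fraction * region_max(img, region)
  threshold_result(mask_from_threshold(img, T, seed_point), T)
}

# Damped Picard fixed-point iteration shared by the volume-adaptive and
# signal-adaptive rules: the threshold and the region statistic it depends
# on are alternated from a 40% SUVmax start, with a period-2 oscillation
# guard. Convergence when |delta T| < 0.1% of SUVmax.
fixed_point_threshold <- function(img, seed_point, update, region = NULL,
                                  max_iter = 50L) {
  suv_max <- region_max(img, region)
  tol <- 1e-3 * suv_max
  T <- 0.40 * suv_max
  T_hist <- T
  mask <- mask_from_threshold(img, T, seed_point)
  for (it in seq_len(max_iter)) {
    if (!any(mask$values))
      return(threshold_result(mask, T, it, converged = FALSE))
    T_new <- update(mask)
    if (abs(T_new - T) < tol) {
      mask <- mask_from_threshold(img, T_new, seed_point)
      return(threshold_result(mask, T_new, it, converged = TRUE))
    }
    if (length(T_hist) >= 2L &&
        abs(T_new - T_hist[length(T_hist) - 1L]) < tol) {
      # period-2 oscillation: settle on the midpoint
      T_mid <- (T_new + T) / 2
      mask <- mask_from_threshold(img, T_mid, seed_point)
      return(threshold_result(mask, T_mid, it, converged = FALSE))
    }
    T <- T_new
    T_hist <- c(T_hist, T)
    mask <- mask_from_threshold(img, T, seed_point)
  }
  threshold_result(mask, T, max_iter, converged = FALSE)
}

#' Parameters of the volume-adaptive threshold rule
#'
#' @param intercept Percent threshold at 1 cm^3 (default 59.1).
#' @param slope Percent decrease per decade of volume (default 18.5).
#' @return An object of class `biehl_params`.
#' @export
biehl_params <- function(intercept = 59.1, slope = 18.5) {
  stopifnot(slope > 0)
  structure(list(intercept = intercept, slope = slope),
            class = "biehl_params")
}

#' Parameters of the signal-adaptive threshold rule
#'
#' @param gain Slope on the mean target SUV (default 0.307).
#' @param offset Additive SUV offset (default 0.588).
#' @return An object of class `black_params`.
#' @export
black_params <- function(gain = 0.307, offset = 0.588) {
  stopifnot(gain > 0)
  structure(list(gain = gain, offset = offset), class = "black_params")
}

#' Parameters of the background-corrected threshold rule
#'
#' @param beta Weight on the 70%-isocontour mean intensity (default 0.15).
#' @param iso_fraction Isocontour level as a fraction of Imax (default 0.70).
#' @return An object of class `nestle_params`.
#' @export
nestle_params <- function(beta = 0.15, iso_fraction = 0.70) {
  stopifnot(iso_fraction > 0, iso_fraction < 1)
  structure(list(beta = beta, iso_fraction = iso_fraction),
            class = "nestle_params")
}

#' Parameters of the contrast-oriented threshold rule
#'
#' @param a_large,b_large Coefficients for lesions of equivalent-sphere
#'   diameter at or above `size_cut_cm` (defaults 0.50, 0.50).
#' @param a_small,b_small Coefficients below the cut (defaults 0.67, 0.60).
#' @param size_cut_cm Diameter cut in cm (default 3).
#' @param iso_fraction Isocontour level for SUVmean (default 0.70).
#' @return An object of class `schaefer_params`.
#' @export
schaefer_params <- function(a_large = 0.50, b_large = 0.50, a_small = 0.67,
                            b_small = 0.60, size_cut_cm = 3,
                            iso_fraction = 0.70) {
  stopifnot(all(c(a_large, b_large, a_small, b_small) > 0), size_cut_cm > 0)
  structure(list(a_large = a_large, b_large = b_large, a_small = a_small,
                 b_small = b_small, size_cut_cm = size_cut_cm,
                 iso_fraction = iso_fraction),
            class = "schaefer_params")
}

equivalent_diameter_cm <- function(volume_cm3) {
  2 * (3 * volume_cm3 / (4 * pi))^(1 / 3)
}

#' Volume-adaptive percentage thresholding
#'
#' The threshold percentage depends on the (unknown) tumour volume, so the
#' circular dependence is resolved by fixed-point iteration from the 40%
#' SUVmax mask: measure the current mask volume in cm^3, update the
#' percentage via [threshold_biehl_pct()], re-threshold, repeat.
#'
#' @inheritParams segment_pct_max
#' @param params A [biehl_params()].
#' @return A `threshold_result`.
#' @export
segment_biehl <- function(img, seed_point, params = biehl_params(),
                          region = NULL) {
  suv_max <- region_max(img, region)
  fixed_point_threshold(img, seed_point, region = region, update = function(mask) {
    v <- max(mask_volume_cm3(mask), 1e-3)
    pct <- min(max(threshold_biehl_pct(v, params$intercept, params$slope), 1), 99)
    pct / 100 * suv_max
  })
}

#' Signal-adaptive SUV thresholding
#'
#' `T = gain * (mean SUV over the current mask) + offset`, iterated to a
#' fixed point from the 40% SUVmax mask.
#'
#' @inheritParams segment_pct_max
#' @param params A [black_params()].
#' @return A `threshold_result`.
#' @export
segment_black <- function(img, seed_point, params = black_params(),
                          region = NULL) {
  fixed_point_threshold(img, seed_point, region = region, update = function(mask) {
    threshold_black(mean(img$values[mask$values]), params$gain, params$offset)
  })
}

#' Background-corrected thresholding
#'
#' Single pass: `I_mean` is the mean intensity inside the 70% Imax
#' isocontour of the lesion component, `I_bkg` the mean over the supplied
#' background mask, and the threshold is `beta * I_mean + I_bkg`.
#'
#' @inheritParams segment_pct_max
#' @param background_mask A [pet_mask()] over a background region disjoint
#'   from the lesion (see [background_shell()]).
#' @param params A [nestle_params()].
#' @return A `threshold_result`.
#' @export
segment_nestle <- function(img, seed_point, background_mask,
                           params = nestle_params(), region = NULL) {
  stopifnot(inherits(background_mask, "pet_mask"), any(background_mask$values))
  i_mean <- isocontour_mean(img, seed_point, params$iso_fraction, region)
  i_bkg <- mean(img$values[background_mask$values])
  T <- threshold_nestle(i_mean, i_bkg, params$beta)
  threshold_result(mask_from_threshold(img, T, seed_point), T)
}

#' Contrast-oriented thresholding
#'
#' The threshold is a fraction of SUVmax combining the 70%-isocontour mean
#' and the background level with size-dependent coefficients. The size
#' class (equivalent-sphere diameter against 3 cm) is first estimated from
#' the 40% SUVmax mask and re-estimated once from the resulting mask (two
#' passes at most). A fraction at or above 1 yields the empty-mask signal.
#'
#' @inheritParams segment_nestle
#' @param params A [schaefer_params()].
#' @return A `threshold_result`.
#' @export
segment_schaefer <- function(img, seed_point, background_mask,
                             params = schaefer_params(), region = NULL) {
  stopifnot(inherits(background_mask, "pet_mask"), any(background_mask$values))
  suv_max <- region_max(img, region)
  suv_mean70 <- isocontour_mean(img, seed_point, params$iso_fraction, region)
  bkg <- mean(img$values[background_mask$values])
  init <- segment_pct_max(img, seed_point, 0.40, region)
  size <- if (equivalent_diameter_cm(mask_volume_cm3(init$mask)) >=
              params$size_cut_cm) "large" else "small"
  for (pass in 1:2) {
    frac <- threshold_schaefer_fraction(
      suv_mean70, bkg, suv_max, size,
      params$a_large, params$b_large, params$a_small, params$b_small)
    if (frac >= 1) {
      empty <- pet_mask(array(FALSE, dim(img$values)), img$spacing)
      return(threshold_result(empty, frac * suv_max, pass, converged = TRUE))
    }
    mask <- mask_from_threshold(img, frac * suv_max, seed_point)
    size_new <- if (equivalent_diameter_cm(mask_volume_cm3(mask)) >=
                    params$size_cut_cm) "large" else "small"
    if (size_new == size) break
    size <- size_new
  }
  threshold_result(mask, frac * suv_max, pass)
}

#' Background shell around a reference lesion
#'
#' The background statistic of the background-corrected and
#' contrast-oriented rules refers to a neighbouring region away from the
#' target; the benchmark supplies it as a shell of voxels whose distance
#' from the lesion's bounding box lies between `inner_mm` and `outer_mm`.
#'
#' @param truth A [pet_mask()] (typically the ground-truth lesion).
#' @param inner_mm,outer_mm Shell distance bounds from the bounding box of
#'   `truth`, mm (defaults 15 and 25).
#' @return A [pet_mask()] of the shell.
#' @export
background_shell <- function(truth, inner_mm = 15, outer_mm = 25) {
  stopifnot(inherits(truth, "pet_mask"), any(truth$values), inner_mm < outer_mm)
  dims <- dim(truth$values)
  idx <- which(truth$values, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  box <- array(FALSE, dims)
  box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  d <- sqrt(cpp_edt(as.logical(box), dims, truth$spacing))
  pet_mask(array(d >= inner_mm & d <= outer_mm, dims), truth$spacing)
}
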