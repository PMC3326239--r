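#' Spatial overlap index (Dice-type)
#'
#' `SOI = 2 |A intersect B| / (|A| + |B|)`, ranging from 0 (no overlap) to
#' 1 (complete overlap). Two empty masks are defined to agree completely
#' (SOI = 1); one empty mask gives 0.
#'
#' @param a,b Congruent [pet_mask()]s.
#' @return SOI in `[0, 1]`.
#' @export
spatial_overlap_index <- function(a, b) {
  stopifnot(inherits(a, "pet_mask"), inherits(b, "pet_mask"))
  stopifnot_congruent(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) return(1)
  2 * sum(a$values & b$values) / (na + nb)
}

#' Voxel classification error
#'
#' `CE = (PCE + NCE) / VoIL * 100%`, where PCE counts background voxels
#' classified as tumour, NCE counts tumour voxels classified as background
#' and VoIL is the reference lesion's voxel count. A grossly over-covering
#' segmentation can push CE above 100%.
#'
#' @param seg Segmentation [pet_mask()].
#' @param ref Nonempty reference [pet_mask()] (the ground truth).
#' @return A list with `pce`, `nce`, `voil` (voxel counts) and
#'   `ce_percent`.
#' @export
classification_error <- function(seg, ref) {
  stopifnot(inherits(seg, "pet_mask"), inherits(ref, "pet_mask"))
  stopifnot_congruent(seg, ref)
  if (!any(ref$values)) stop("reference mask is empty", call. = FALSE)
  pce <- sum(seg$values & !ref$values)
  nce <- sum(ref$values & !seg$values)
  voil <- sum(ref$values)
  list(pce = pce, nce = nce, voil = voil,
       ce_percent = 100 * (pce + nce) / voil)
}

#' Relative volume error
#'
#' `100 * (V_seg - V_ref) / V_ref` with volumes measured as voxel count
#' times voxel volume; underestimation is negative.
#'
#' @inheritParams classification_error
#' @return Relative volume error in percent.
#' @export
relative_volume_error <- function(seg, ref) {
  stopifnot(inherits(seg, "pet_mask"), inherits(ref, "pet_mask"))
  stopifnot_congruent(seg, ref)
  if (!any(ref$values)) stop("reference mask is empty", call. = FALSE)
  100 * (mask_volume_cm3(seg) - mask_volume_cm3(ref)) / mask_volume_cm3(ref)
}

#' Two-tailed paired t-test
#'
#' The classic paired t on the differences `x - y`, with the two-sided p
#' value from the t distribution on `n - 1` degrees of freedom. Degenerate
#' inputs are reported rather than erroring: identical lists give `t = 0`
#' with `p = 1` by convention, and constant nonzero differences give an
#' infinite t (flagged via `degenerate = TRUE`) with `p = 0`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`.
#' @return A list with `t_statistic`, `p_value`, `df`, `mean_difference`
#'   and `degenerate`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0)
      return(list(t_statistic = 0, p_value = 1, df = n - 1,
                  mean_difference = 0, degenerate = TRUE))
    return(list(t_statistic = sign(mean(d)) * Inf, p_value = 0, df = n - 1,
                mean_difference = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t_statistic = t, p_value = 2 * stats::pt(-abs(t), df = n - 1),
       df = n - 1, mean_difference = mean(d), degenerate = FALSE)
}

#' Score one segmentation against the reference
#'
#' @inheritParams classification_error
#' @param method Optional method label.
#' @param case Optional case label.
#' @return A one-row `data.frame` with SOI, PCE/NCE/VoIL, CE, both volumes
#'   (cm^3) and the relative volume error.
#' @export
metrics_record <- function(seg, ref, method = NA_character_, case = NA) {
  ce <- classification_error(seg, ref)
  data.frame(case = case, method = method,
             soi = spatial_overlap_index(seg, ref),
             pce = ce$pce, nce = ce$nce, voil = ce$voil,
             ce_percent = ce$ce_percent,
             seg_volume_cm3 = mask_volume_cm3(seg),
             ref_volume_cm3 = mask_volume_cm3(ref),
             rel_vol_err_percent = relative_volume_error(seg, ref),
             stringsAsFactors = FALSE)
}

#' Cohort-level summary of per-case metrics
#'
#' Aggregates a long-format results table (one row per case x method, as
#' produced by [metrics_record()] / [run_benchmark()]) into one row per
#' method: mean, SD and range of SOI; mean and SD of the relative volume
#' error and classification error; mean segmented volume; and the paired
#' two-tailed t-test p value of the segmented volumes against the
#' reference volumes.
#'
#' @param records `data.frame` with at least `method`, `soi`, `ce_percent`,
#'   `seg_volume_cm3`, `ref_volume_cm3`, `rel_vol_err_percent`.
#' @return A `data.frame` with one row per method.
#' @export
summarize_cohort <- function(records) {
  stopifnot(nrow(records) >= 1)
  records <- records[!is.na(records$soi), , drop = FALSE]
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  do.call(rbind, lapply(split(records, records$method), function(r) {
    p <- if (nrow(r) >= 2)
      paired_ttest(r$seg_volume_cm3, r$ref_volume_cm3)$p_value else NA_real_
    data.frame(method = r$method[1], n_cases = nrow(r),
               soi_mean = mean(r$soi), soi_sd = sd0(r$soi),
               soi_min = min(r$soi), soi_max = max(r$soi),
               volume_mean_cm3 = mean(r$seg_volume_cm3),
               volume_sd_cm3 = sd0(r$seg_volume_cm3),
               ref_volume_mean_cm3 = mean(r$ref_volume_cm3),
               rel_err_mean = mean(r$rel_vol_err_percent),
               rel_err_sd = sd0(r$rel_vol_err_percent),
               ce_mean = mean(r$ce_percent), ce_sd = sd0(r$ce_percent),
               p_value = p,
               stringsAsFactors = FALSE)
  }))
}
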