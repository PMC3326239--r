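#' Benchmark configuration
#'
#' Describes a full comparative run: the synthetic cohort, the
#' preprocessing chain, the methods to compare and any per-method parameter
#' overrides. Defaults follow the published parameter values throughout
#' (6 mm / 2-iteration bilateral filter; 6 mm / 30-iteration Landweber;
#' the 40% SUVmax rule; the published adaptive-threshold coefficients).
#'
#' @param n_cases Number of cohort cases (default 7).
#' @param n_replicates Independent noise replicates per case (default 1);
#'   replicate seeds are derived from each case's seed.
#' @param master_seed Master seed recorded in every output (default 1).
#' @param spec_template Optional [phantom_spec()] template for the cohort.
#' @param methods Character vector of methods to run; any of
#'   `"suvmax40"`, `"biehl"`, `"black"`, `"nestle"`, `"schaefer"`,
#'   `"levelset"`, `"em"`, `"fcm"`, `"fcm_sw"`.
#' @param margin_mm Margin around the reference lesion's bounding box
#'   defining the analysis region each method sees (default 32 mm; wide
#'   enough to hold the 15-25 mm background shell).
#' @param bilateral,landweber Preprocessing parameter objects.
#' @param method_params Named list of per-method parameter overrides, e.g.
#'   `list(fcm_sw = fcm_sw_params(beta0 = 0.5))`.
#' @param out_dir Optional output directory for CSV reports (and masks).
#' @param write_masks Write each segmentation as NIfTI under `out_dir`.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_cases = 7, n_replicates = 1, master_seed = 1,
                             spec_template = NULL,
                             methods = pet_methods(), margin_mm = 32,
                             bilateral = bilateral_params(),
                             landweber = landweber_params(),
                             method_params = list(), out_dir = NULL,
                             write_masks = FALSE) {
  methods <- match.arg(methods, pet_methods(), several.ok = TRUE)
  stopifnot(n_cases >= 1, n_replicates >= 1, margin_mm > 0)
  if (length(bad <- setdiff(names(method_params), pet_methods())))
    stop("unknown method in `method_params`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(n_cases = as.integer(n_cases),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 spec_template = spec_template, methods = methods,
                 margin_mm = margin_mm, bilateral = bilateral,
                 landweber = landweber, method_params = method_params,
                 out_dir = out_dir, write_masks = isTRUE(write_masks)),
            class = "benchmark_config")
}

#' The nine benchmarked segmentation methods
#'
#' @return Character vector of method identifiers.
#' @export
pet_methods <- function() {
  c("suvmax40", "biehl", "black", "nestle", "schaefer",
    "levelset", "em", "fcm", "fcm_sw")
}

# Bounding box of a mask expanded by margin_mm, clipped to the grid.
lesion_region_box <- function(truth, margin_mm) {
  dims <- dim(truth$values)
  idx <- which(truth$values, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  pad <- ceiling(margin_mm / truth$spacing)
  list(lo = pmax(lo - pad, 1L), hi = pmin(hi + pad, dims))
}

crop_values <- function(values, box) {
  values[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3],
         drop = FALSE]
}

embed_mask <- function(mask_small, dims_full, box) {
  full <- array(FALSE, dims_full)
  full[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <-
    mask_small$values
  pet_mask(full, mask_small$spacing)
}

#' Run one segmentation method by name
#'
#' Thin dispatcher used by the benchmark; `params` overrides the method's
#' defaults (a parameter object for the thresholding / level-set /
#' clustering families, or a named list of arguments for `suvmax40`, `em`
#' and `fcm`).
#'
#' @param img A [pet_volume()] (typically preprocessed).
#' @param method One of [pet_methods()].
#' @param seed_point Length-3 voxel index inside the lesion.
#' @param background_mask Background [pet_mask()]; required by `nestle`
#'   and `schaefer`.
#' @param params Optional parameter override.
#' @return A [pet_mask()].
#' @export
segment_method <- function(img, method, seed_point, background_mask = NULL,
                           params = NULL) {
  method <- match.arg(method, pet_methods())
  need_bkg <- method %in% c("nestle", "schaefer")
  if (need_bkg && is.null(background_mask))
    stop(sprintf("method '%s' requires `background_mask`", method),
         call. = FALSE)
  as_mask <- function(x) if (inherits(x, "threshold_result")) x$mask else x
  arg1 <- function(default) if (is.null(params)) default else params
  switch(method,
    suvmax40 = as_mask(do.call(segment_pct_max,
      c(list(img, seed_point), if (is.null(params)) list() else params))),
    biehl = as_mask(segment_biehl(img, seed_point, arg1(biehl_params()))),
    black = as_mask(segment_black(img, seed_point, arg1(black_params()))),
    nestle = as_mask(segment_nestle(img, seed_point, background_mask,
                                    arg1(nestle_params()))),
    schaefer = as_mask(segment_schaefer(img, seed_point, background_mask,
                                        arg1(schaefer_params()))),
    levelset = segment_levelset(img, seed_point,
                                params = arg1(levelset_params())),
    em = do.call(em_segment,
      c(list(img, seed_point), if (is.null(params)) list() else params)),
    fcm = do.call(segment_fcm,
      c(list(img, seed_point), if (is.null(params)) list() else params)),
    fcm_sw = segment_fcm_sw(img, seed_point, arg1(fcm_sw_params())))
}

#' Run the full comparative benchmark
#'
#' Generates the synthetic cohort, then for every case (and noise
#' replicate): restores the image with the two-step preprocessing chain,
#' runs each configured method inside the lesion analysis region (the
#' reference bounding box plus `margin_mm`, emulating a clinician-placed
#' VOI, with a 15-25 mm background shell for the rules that need one), and
#' scores the result against the ground truth. Fully deterministic given
#' `master_seed`. A method failing on a case yields a flagged row, not an
#' error.
#'
#' @param config A [benchmark_config()].
#' @return A list with `results` (long-format `data.frame`: one row per
#'   case x replicate x method), `summary` (per-method aggregate in the
#'   style of a cohort report: mean/SD/range of SOI, mean volumes, relative
#'   errors, CE, paired-t p values), `config`, and `parameter_log` (the
#'   resolved parameter set per method). When `config$out_dir` is set,
#'   `results.csv` and `summary.csv` (and optionally the masks as NIfTI)
#'   are written there.
#' @export
run_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  cohort <- make_cohort(config$n_cases, config$spec_template,
                        config$master_seed)
  default_params <- list(
    suvmax40 = list(fraction = 0.40), biehl = biehl_params(),
    black = black_params(), nestle = nestle_params(),
    schaefer = schaefer_params(), levelset = levelset_params(),
    em = list(K = 3), fcm = list(K_init = 9, K_target = 3, b = 2),
    fcm_sw = fcm_sw_params())
  params <- utils::modifyList(default_params, config$method_params)
  rows <- list()
  for (i in seq_len(config$n_cases)) {
    case <- cohort[[i]]
    box <- lesion_region_box(case$truth, config$margin_mm)
    truth_c <- pet_mask(crop_values(case$truth$values, box),
                        case$truth$spacing)
    bkg <- background_shell(truth_c)
    clean <- if (config$n_replicates > 1L) {
      spec0 <- case$spec
      spec0$noise_sigma <- 0
      make_phantom(spec0)$image    # blurred noise-free image, reused below
    } else NULL
    for (r in seq_len(config$n_replicates)) {
      spec_r <- case$spec
      spec_r$seed <- (spec_r$seed + 7717L * (r - 1L)) %% .Machine$integer.max
      img <- if (r == 1L) case$image
             else apply_phantom_noise(clean, spec_r)
      img_c <- pet_volume(crop_values(img$values, box), img$spacing,
                          img$units)
      pre <- preprocess_volume(img_c, config$bilateral, config$landweber)
      seed_pt <- hottest_voxel(pre, within = truth_c)
      for (m in config$methods) {
        res <- tryCatch(
          segment_method(pre, m, seed_pt, background_mask = bkg,
                         params = params[[m]]),
          error = function(e) e)
        if (inherits(res, "error")) {
          row <- data.frame(case = i, replicate = r, method = m, soi = NA_real_,
                            pce = NA, nce = NA, voil = sum(truth_c$values),
                            ce_percent = NA_real_, seg_volume_cm3 = NA_real_,
                            ref_volume_cm3 = mask_volume_cm3(truth_c),
                            rel_vol_err_percent = NA_real_,
                            failed = TRUE, error = conditionMessage(res),
                            stringsAsFactors = FALSE)
        } else {
          row <- metrics_record(res, truth_c, method = m, case = i)
          row <- cbind(row[1], replicate = r, row[-1], failed = FALSE,
                       error = "")
          if (config$write_masks && !is.null(config$out_dir)) {
            dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
            write_mask(embed_mask(res, dim(case$truth$values), box),
                       file.path(config$out_dir,
                                 sprintf("case%02d_rep%02d_%s.nii.gz", i, r, m)))
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  results <- do.call(rbind, rows)
  results$master_seed <- config$master_seed
  # aggregate replicates per case before the cohort summary, so each case
  # contributes one (mean) value, mirroring a per-patient analysis
  ok <- results[!results$failed, , drop = FALSE]
  per_case <- do.call(rbind, lapply(
    split(ok, interaction(ok$case, ok$method, drop = TRUE)), function(r) {
      data.frame(case = r$case[1], method = r$method[1], soi = mean(r$soi),
                 ce_percent = mean(r$ce_percent),
                 seg_volume_cm3 = mean(r$seg_volume_cm3),
                 ref_volume_cm3 = r$ref_volume_cm3[1],
                 rel_vol_err_percent = mean(r$rel_vol_err_percent),
                 stringsAsFactors = FALSE)
    }))
  summary <- summarize_cohort(per_case)
  parameter_log <- lapply(params[config$methods], function(p) {
    if (is.list(p)) unclass(p) else p
  })
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  list(results = results, summary = summary, config = config,
       parameter_log = parameter_log)
}

#' Bar-chart report of a benchmark summary
#'
#' Three panels in the style of a cohort report: mean segmented volumes
#' (with the reference), mean relative volume errors, and mean
#' classification errors, each with SD error bars.
#'
#' @param summary The `summary` table from [run_benchmark()].
#' @return Invisibly, `summary`.
#' @export
plot_benchmark <- function(summary) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  bars <- function(h, s, main, ylab, extra = NULL, extra_lab = NULL) {
    nm <- summary$method
    if (!is.null(extra)) { h <- c(extra, h); s <- c(0, s); nm <- c(extra_lab, nm) }
    ylim <- range(0, h + s, h - s)
    mid <- graphics::barplot(h, names.arg = nm, las = 2, main = main,
                             ylab = ylab, ylim = ylim)
    nz <- s > 0    # zero-length error bars cannot be drawn
    if (any(nz))
      graphics::arrows(mid[nz], (h - s)[nz], mid[nz], (h + s)[nz],
                       angle = 90, code = 3, length = 0.03)
  }
  bars(summary$volume_mean_cm3, summary$volume_sd_cm3, "Mean volumes",
       expression(cm^3), extra = summary$ref_volume_mean_cm3[1],
       extra_lab = "Reference")
  bars(summary$rel_err_mean, summary$rel_err_sd, "Relative volume error", "%")
  bars(summary$ce_mean, summary$ce_sd, "Classification error", "%")
  invisible(summary)
}
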