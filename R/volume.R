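#' 3-D PET image volume
#'
#' The universal carrier for raw, SUV, filtered and deconvolved images: a
#' 3-D array of finite real intensities plus the physical voxel size in mm
#' along each axis and a units tag.
#'
#' @param values 3-D numeric array of intensities.
#' @param spacing Numeric length-3 vector of voxel size in mm (all > 0).
#' @param units Either `"raw"` (e.g. activity concentration in Bq/ml) or
#'   `"suv"` (standardized uptake values).
#' @return An object of class `pet_volume`: a list with elements `values`,
#'   `spacing` and `units`.
#' @seealso [pet_mask()], [to_suv()]
#' @export
pet_volume <- function(values, spacing = c(2, 2, 2), units = c("raw", "suv")) {
  units <- match.arg(units)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  if (any(!is.finite(values)))
    stop("image intensities must all be finite", call. = FALSE)
  structure(list(values = values, spacing = spacing, units = units),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_volume> %d x %d x %d voxels @ %s mm [%s]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              x$units))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary lesion mask
#'
#' A 3-D logical grid geometrically congruent to a [pet_volume()]; used for
#' segmentations and ground truth.
#'
#' @param values 3-D logical (or 0/1 numeric) array.
#' @param spacing Voxel size in mm per axis.
#' @return An object of class `pet_mask` with elements `values` (logical
#'   array) and `spacing`.
#' @export
pet_mask <- function(values, spacing = c(2, 2, 2)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (!is.logical(values)) {
    if (any(!values %in% c(0, 1)))
      stop("mask values must be logical or 0/1", call. = FALSE)
    storage.mode(values) <- "logical"
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  structure(list(values = values, spacing = spacing), class = "pet_mask")
}

#' @export
print.pet_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_mask> %d x %d x %d voxels @ %s mm; %d voxels on (%.2f cm^3)\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              sum(x$values), mask_volume_cm3(x)))
  invisible(x)
}

stopifnot_congruent <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grids have different shapes", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("grids have different voxel spacing", call. = FALSE)
  invisible(TRUE)
}

#' Physical volume of a mask
#'
#' @param mask A [pet_mask()].
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$values) * prod(mask$spacing) / 1000
}

#' SUV calibration constants
#'
#' Injection and patient data needed to convert an activity-concentration
#' image into standardized uptake values.
#'
#' @param injected_activity_bq Administered activity in Bq (> 0).
#' @param body_weight_g Patient body weight in g (> 0).
#' @param decay_corrected Whether the image is already decay-corrected to
#'   injection time (the conversion assumes it is).
#' @return An object of class `suv_calibration`.
#' @export
suv_calibration <- function(injected_activity_bq, body_weight_g,
                            decay_corrected = TRUE) {
  if (!is.finite(injected_activity_bq) || injected_activity_bq <= 0)
    stop("`injected_activity_bq` must be > 0", call. = FALSE)
  if (!is.finite(body_weight_g) || body_weight_g <= 0)
    stop("`body_weight_g` must be > 0", call. = FALSE)
  structure(list(injected_activity_bq = injected_activity_bq,
                 body_weight_g = body_weight_g,
                 decay_corrected = isTRUE(decay_corrected)),
            class = "suv_calibration")
}

#' Convert an activity-concentration image to SUV
#'
#' SUV is the decay-corrected activity per unit mass of tissue normalized by
#' the administered activity per unit body weight:
#' `SUV = concentration (Bq/ml) * body weight (g) / injected activity (Bq)`,
#' taking tissue density as 1 g/ml.
#'
#' @param img A [pet_volume()] in `"raw"` units (Bq/ml).
#' @param cal A [suv_calibration()].
#' @return A [pet_volume()] with `units = "suv"`.
#' @export
to_suv <- function(img, cal) {
  stopifnot(inherits(img, "pet_volume"), inherits(cal, "suv_calibration"))
  if (img$units == "suv")
    stop("image is already in SUV units", call. = FALSE)
  pet_volume(img$values * cal$body_weight_g / cal$injected_activity_bq,
             img$spacing, units = "suv")
}

#' Read / write volumes and masks as NIfTI
#'
#' Round-trips the voxel grid and mm spacing through NIfTI-1 files (plain
#' `.nii` or compressed `.nii.gz`). Masks are stored as 0/1 integers and
#' reload as logical grids.
#'
#' @param path File path.
#' @param img,mask Objects to write.
#' @param units Units tag to attach when reading an image.
#' @return `read_volume()` a [pet_volume()]; `read_mask()` a [pet_mask()];
#'   the writers return the path invisibly.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
read_volume <- function(path, units = c("raw", "suv")) {
  nii <- RNifti::readNifti(path)
  vals <- as.array(nii)
  attributes(vals) <- list(dim = dim(vals))   # drop NIfTI header attributes
  pet_volume(vals, spacing = RNifti::pixdim(nii)[1:3],
             units = match.arg(units))
}

#' @rdname nifti_io
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "pet_volume"))
  nii <- RNifti::asNifti(img$values)
  RNifti::pixdim(nii) <- img$spacing
  RNifti::writeNifti(nii, path, datatype = "float")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path) {
  nii <- RNifti::readNifti(path)
  vals <- as.array(nii) != 0
  attributes(vals) <- list(dim = dim(vals))
  pet_mask(vals, spacing = RNifti::pixdim(nii)[1:3])
}

#' @rdname nifti_io
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "pet_mask"))
  nii <- RNifti::asNifti(array(as.integer(mask$values), dim(mask$values)))
  RNifti::pixdim(nii) <- mask$spacing
  RNifti::writeNifti(nii, path, datatype = "uint8")
  invisible(path)
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
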