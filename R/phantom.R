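#' Describe one lesion component
#'
#' Phantom lesions are built from overlapping spheres/ellipsoids with
#' different uptake levels: overlapping components form irregular,
#' heterogeneous lesions and a nested component with uptake below its
#' parent's models a necrotic core.
#'
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param centre Length-3 centre in mm (continuous world coordinates;
#'   voxel centres sit at `(index - 0.5) * spacing`).
#' @param radii Radii in mm; one value for a sphere, three for an ellipsoid.
#' @param uptake Uptake level in SUV assigned inside the component (>= 0).
#' @return An object of class `lesion_component`.
#' @export
lesion_component <- function(shape = c("sphere", "ellipsoid"), centre, radii,
                             uptake) {
  shape <- match.arg(shape)
  centre <- as.numeric(centre)
  radii <- as.numeric(radii)
  if (shape == "sphere" && length(radii) == 1L) radii <- rep(radii, 3L)
  if (length(centre) != 3L || length(radii) != 3L)
    stop("`centre` and `radii` must have length 3", call. = FALSE)
  if (any(radii <= 0)) stop("radii must be > 0", call. = FALSE)
  if (!is.finite(uptake) || uptake < 0) stop("uptake must be >= 0", call. = FALSE)
  structure(list(shape = shape, centre = centre, radii = radii,
                 uptake = uptake), class = "lesion_component")
}

#' Declarative description of a synthetic PET case
#'
#' Defaults emulate a neck FDG acquisition: a 96^3 grid at 2 mm spacing, a
#' soft-tissue background of 2 SUV, system blur of 6 mm FWHM and additive
#' Gaussian post-reconstruction noise.
#'
#' @param grid_shape Integer length-3 grid size.
#' @param spacing Voxel size in mm per axis.
#' @param background_uptake Background level in SUV (>= 0).
#' @param components List of [lesion_component()]s painted in order (later
#'   components override earlier ones where they overlap). At least one
#'   component must exceed the background uptake.
#' @param blur_fwhm System PSF blur, mm FWHM (0 disables).
#' @param noise_sigma Standard deviation of additive Gaussian noise applied
#'   after the blur, in SUV (0 disables).
#' @param noise_model `"gaussian"` (default) or `"poisson"`; the Poisson
#'   option rescales intensities so that the background mean acts as the
#'   expected count per voxel divided by `noise_sigma^2`.
#' @param seed Integer seed making the noise draw reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), spacing = c(2, 2, 2),
                         background_uptake = 2, components,
                         blur_fwhm = 6, noise_sigma = 0.3,
                         noise_model = c("gaussian", "poisson"), seed = 1) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            background_uptake >= 0, blur_fwhm >= 0, noise_sigma >= 0)
  if (inherits(components, "lesion_component")) components <- list(components)
  if (!length(components) ||
      !any(vapply(components, function(cc) cc$uptake, 0) > background_uptake))
    stop("need at least one component with uptake above background",
         call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 background_uptake = background_uptake,
                 components = components, blur_fwhm = blur_fwhm,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Voxel-centre coordinate vectors (mm) for a grid.
voxel_centres <- function(grid_shape, spacing) {
  lapply(1:3, function(a) (seq_len(grid_shape[a]) - 0.5) * spacing[a])
}

# Logical array of voxels whose centres lie inside the component.
component_mask <- function(comp, grid_shape, spacing) {
  cc <- voxel_centres(grid_shape, spacing)
  dx2 <- ((cc[[1]] - comp$centre[1]) / comp$radii[1])^2
  dy2 <- ((cc[[2]] - comp$centre[2]) / comp$radii[2])^2
  dz2 <- ((cc[[3]] - comp$centre[3]) / comp$radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Generate a synthetic PET volume with known ground truth
#'
#' Paints the piecewise-constant uptake map described by `spec`, records the
#' ground-truth lesion mask (union of voxels whose centres fall inside any
#' component with uptake above background, before blur and noise), then
#' applies the system blur and the noise model. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` ([pet_volume()], SUV units),
#'   `truth` ([pet_mask()]) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vals <- array(spec$background_uptake, spec$grid_shape)
  truth <- array(FALSE, spec$grid_shape)
  any_inside <- FALSE
  for (comp in spec$components) {
    m <- component_mask(comp, spec$grid_shape, spec$spacing)
    if (any(m)) any_inside <- TRUE
    vals[m] <- comp$uptake
    if (comp$uptake > spec$background_uptake) truth[m] <- TRUE
  }
  if (!any_inside)
    stop("degenerate spec: grid too small to contain any component",
         call. = FALSE)
  img <- pet_volume(vals, spec$spacing, units = "suv")
  if (spec$blur_fwhm > 0) img <- apply_system_blur(img, spec$blur_fwhm)
  img <- apply_phantom_noise(img, spec)
  list(image = img, truth = pet_mask(truth, spec$spacing), spec = spec)
}

# Post-blur noise draw, seeded from the spec; shared by make_phantom() and
# the benchmark's per-replicate regeneration so both produce identical
# images for a given spec.
apply_phantom_noise <- function(img, spec) {
  if (spec$noise_sigma <= 0) return(img)
  img$values <- with_local_seed(spec$seed, {
    if (spec$noise_model == "gaussian") {
      img$values + array(stats::rnorm(length(img$values), 0, spec$noise_sigma),
                         dim(img$values))
    } else {
      # scaled Poisson: variance ~= noise_sigma^2 at background level
      s <- max(spec$background_uptake, 1e-6) / spec$noise_sigma^2
      array(stats::rpois(length(img$values), pmax(img$values, 0) * s) / s,
            dim(img$values))
    }
  })
  img
}

#' Serialize a phantom description to a flat YAML config
#'
#' Writes every scalar field (grid, spacing, background, blur, noise model
#' and seed) plus one block per lesion component, so a case can be
#' regenerated exactly from its config file.
#'
#' @param spec A [phantom_spec()].
#' @param path Output file path (`.yaml`).
#' @return `write_phantom_spec()` returns `path` invisibly;
#'   `read_phantom_spec()` returns the reconstructed [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  obj <- list(grid_shape = spec$grid_shape, spacing = spec$spacing,
              background_uptake = spec$background_uptake,
              blur_fwhm = spec$blur_fwhm, noise_sigma = spec$noise_sigma,
              noise_model = spec$noise_model, seed = spec$seed,
              components = lapply(spec$components, function(cc)
                list(shape = cc$shape, centre = cc$centre,
                     radii = cc$radii, uptake = cc$uptake)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  phantom_spec(grid_shape = unlist(obj$grid_shape),
               spacing = unlist(obj$spacing),
               background_uptake = obj$background_uptake,
               components = lapply(obj$components, function(cc)
                 lesion_component(cc$shape, unlist(cc$centre),
                                  unlist(cc$radii), cc$uptake)),
               blur_fwhm = obj$blur_fwhm, noise_sigma = obj$noise_sigma,
               noise_model = obj$noise_model, seed = obj$seed)
}

#' Apply an isotropic Gaussian system blur
#'
#' Emulates the scanner point-spread function as a separable Gaussian with
#' `sigma = FWHM / 2.3548` along each axis (in mm, so anisotropic voxels are
#' handled correctly). Mirror boundaries conserve total intensity.
#'
#' @param img A [pet_volume()].
#' @param fwhm_mm Blur full-width at half-maximum in mm; 0 is the identity.
#' @return A blurred [pet_volume()].
#' @export
apply_system_blur <- function(img, fwhm_mm) {
  stopifnot(inherits(img, "pet_volume"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(img)
  gaussian_smooth(img, fwhm_mm)
}

#' Separable Gaussian smoothing of a volume
#'
#' @param img A [pet_volume()].
#' @param fwhm_mm Kernel FWHM in mm (`sigma = fwhm / 2.3548`).
#' @param radius Optional kernel half-width in voxels per axis; defaults to
#'   `ceiling(3.5 * sigma)` per axis.
#' @return The smoothed [pet_volume()].
#' @export
gaussian_smooth <- function(img, fwhm_mm, radius = NULL) {
  stopifnot(inherits(img, "pet_volume"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(img)
  sigma_vox <- (fwhm_mm / 2.3548) / img$spacing
  if (is.null(radius)) radius <- pmax(1L, as.integer(ceiling(3.5 * sigma_vox)))
  radius <- as.integer(rep(radius, length.out = 3L))
  out <- cpp_gauss_blur(as.numeric(img$values), dim(img$values),
                        sigma_vox, radius)
  pet_volume(array(out, dim(img$values)), img$spacing, img$units)
}

# Ellipsoid radii (mm) for a target volume with mild per-axis anisotropy.
radii_for_volume <- function(volume_cm3, anisotropy = c(1, 1, 1)) {
  r_eq <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  r_eq * anisotropy / prod(anisotropy)^(1 / 3)
}

#' Build a heterogeneous rim/core lesion
#'
#' A mildly anisotropic ellipsoid of high uptake (`contrast` times
#' background) containing a nested low-uptake core (`core_contrast` times
#' background) — the canonical heterogeneous lesion with a necrotic-like
#' centre. The core still exceeds background, so it belongs to the
#' ground-truth lesion.
#'
#' @param volume_cm3 Total lesion volume (outer ellipsoid), cm^3.
#' @param centre_mm Lesion centre in mm.
#' @param background Background uptake (SUV).
#' @param contrast Rim uptake as a multiple of background (default 4).
#' @param core_contrast Core uptake as a multiple of background (default 1.5).
#' @param core_fraction Core radius as a fraction of the lesion radius.
#' @param anisotropy Per-axis stretch factors (geometric mean 1 preserves
#'   the volume).
#' @return A list of two [lesion_component()]s (rim then core).
#' @export
heterogeneous_lesion <- function(volume_cm3, centre_mm, background = 2,
                                 contrast = 4, core_contrast = 1.5,
                                 core_fraction = 0.5,
                                 anisotropy = c(1, 1, 1)) {
  radii <- radii_for_volume(volume_cm3, anisotropy)
  list(lesion_component("ellipsoid", centre_mm, radii, contrast * background),
       lesion_component("ellipsoid", centre_mm, radii * core_fraction,
                        core_contrast * background))
}

#' Generate a reproducible synthetic cohort
#'
#' Draws `n_cases` phantoms whose total lesion volumes are uniform on
#' `volume_range_cm3` (default 4-33 cm^3), each a heterogeneous rim/core
#' ellipsoid with per-case shape anisotropy and centre jitter. Per-case
#' seeds are derived from `master_seed`, so two runs with the same master
#' seed produce identical cohorts.
#'
#' @param n_cases Number of cases (>= 1).
#' @param spec_template Optional [phantom_spec()] whose grid, background,
#'   blur and noise settings are reused (its components are replaced per
#'   case). `NULL` uses the package defaults.
#' @param master_seed Integer master seed.
#' @param volume_range_cm3 Range to draw lesion volumes from.
#' @return A list of cases, each as returned by [make_phantom()].
#' @export
make_cohort <- function(n_cases = 7, spec_template = NULL, master_seed = 1,
                        volume_range_cm3 = c(4, 33)) {
  stopifnot(n_cases >= 1)
  if (is.null(spec_template)) {
    spec_template <- phantom_spec(
      components = list(lesion_component("sphere", c(96, 96, 96), 15, 8)))
  }
  draws <- with_local_seed(master_seed, {
    list(volumes = stats::runif(n_cases, volume_range_cm3[1], volume_range_cm3[2]),
         aniso = matrix(exp(stats::rnorm(3 * n_cases, 0, 0.08)), ncol = 3),
         jitter = matrix(stats::runif(3 * n_cases, -4, 4), ncol = 3),
         seeds = sample.int(2^30, n_cases))
  })
  centre0 <- spec_template$grid_shape * spec_template$spacing / 2
  lapply(seq_len(n_cases), function(i) {
    comps <- heterogeneous_lesion(
      draws$volumes[i], centre0 + draws$jitter[i, ],
      background = spec_template$background_uptake,
      anisotropy = draws$aniso[i, ])
    spec <- spec_template
    spec$components <- comps
    spec$seed <- draws$seeds[i]
    make_phantom(spec)
  })
}
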