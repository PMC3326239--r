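# Small fixture builders shared across the suite; everything is generated
# in code so the whole test corpus is deterministic and text-only.

# Two-level image: a cuboid lesion of `level` inside a flat background.
two_level_volume <- function(dims = c(16, 16, 16), lesion = 5:10,
                             level = 10, background = 0, spacing = 2) {
  v <- array(background, dims)
  v[lesion, lesion, lesion] <- level
  pet_volume(v, spacing, units = "suv")
}

# Noiseless blurred sphere at a given contrast, cropped to a working box;
# returns image, truth, and the preprocessed volume on request.
sphere_case <- function(radius_mm = 15, contrast = 8, background = 1,
                        grid = 72, spacing = 2, blur = 6, noise = 0,
                        seed = 1) {
  centre <- rep(grid * spacing / 2, 3)
  spec <- phantom_spec(grid_shape = rep(grid, 3), spacing = spacing,
                       background_uptake = background,
                       components = lesion_component("sphere", centre,
                                                     radius_mm,
                                                     contrast * background),
                       blur_fwhm = blur, noise_sigma = noise, seed = seed)
  make_phantom(spec)
}

# Rim/core heterogeneous case under the cohort's default conditions.
hetero_case <- function(volume_cm3 = 15, background = 2, noise = 0.3,
                        grid = 72, spacing = 2, seed = 1) {
  centre <- rep(grid * spacing / 2, 3)
  spec <- phantom_spec(grid_shape = rep(grid, 3), spacing = spacing,
                       background_uptake = background,
                       components = heterogeneous_lesion(volume_cm3, centre,
                                                         background = background),
                       blur_fwhm = 6, noise_sigma = noise, seed = seed)
  make_phantom(spec)
}

# Crop a phantom to its lesion analysis region and preprocess, mirroring
# the benchmark pipeline; returns list(pre, truth, seed_point, bkg).
prepared_case <- function(ph, margin_mm = 32) {
  box <- petseg:::lesion_region_box(ph$truth, margin_mm)
  truth <- pet_mask(petseg:::crop_values(ph$truth$values, box),
                    ph$truth$spacing)
  img <- pet_volume(petseg:::crop_values(ph$image$values, box),
                    ph$image$spacing, ph$image$units)
  pre <- preprocess_volume(img)
  list(pre = pre, truth = truth,
       seed_point = hottest_voxel(pre, within = truth),
       bkg = background_shell(truth))
}

random_mask <- function(dims = c(6, 6, 6), p = 0.4, spacing = 2) {
  pet_mask(array(stats::runif(prod(dims)) < p, dims), spacing)
}
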