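#' Geometric level-set parameters
#'
#' The front evolves with outward speed `g(|grad I|) * (nu - eps * kappa)`
#' where `kappa` is the mean curvature of the front and
#' `g(s) = 1 / (1 + (s / lambda)^2)` is the edge-stopping function on the
#' gradient magnitude of the image: the speed is proportional to the
#' curvature forces and vanishes at strong image gradients.
#'
#' @param balloon Expansion force nu in mm per unit time (negative values
#'   shrink the front).
#' @param curvature Curvature weight eps (mm^2 per unit time); regularizes
#'   the front and shrinks high-curvature bumps.
#' @param lambda Gradient scale of the edge-stopping term, in image units
#'   per mm. `NULL` (default) adapts to contrast: the 50th percentile of
#'   nonzero gradient magnitudes over the image.
#' @param time_step Explicit Euler step. `NULL` (default) picks a CFL-safe
#'   step each iteration from the current maximum speed.
#' @param reinit_every Reinitialize phi to a signed distance every this many
#'   steps (default 20).
#' @param max_iterations Iteration cap (default 200).
#' @param convergence_tol Converged when the fraction of voxels changing
#'   sign per step stays below this for 5 consecutive steps.
#' @return An object of class `levelset_params`.
#' @export
levelset_params <- function(balloon = 0.3, curvature = 1.0, lambda = NULL,
                            time_step = NULL, reinit_every = 20,
                            max_iterations = 200, convergence_tol = 2e-3) {
  stopifnot(max_iterations >= 1, reinit_every >= 1, convergence_tol >= 0)
  structure(list(balloon = balloon, curvature = curvature, lambda = lambda,
                 time_step = time_step, reinit_every = as.integer(reinit_every),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "levelset_params")
}

#' Signed Euclidean distance to a mask boundary
#'
#' Negative inside the mask, positive outside, in mm; distances are pulled
#' half a voxel inwards/outwards so the zero crossing sits on the mask
#' boundary rather than on voxel centres.
#'
#' @param mask A [pet_mask()].
#' @return A 3-D numeric array of signed distances (mm).
#' @export
signed_distance <- function(mask) {
  stopifnot(inherits(mask, "pet_mask"))
  dims <- dim(mask$values)
  if (!any(mask$values)) stop("mask is empty", call. = FALSE)
  h <- min(mask$spacing) / 2
  if (all(mask$values)) return(array(-h, dims))
  d_in <- sqrt(cpp_edt(as.logical(mask$values), dims, mask$spacing))
  d_out <- sqrt(cpp_edt(as.logical(!mask$values), dims, mask$spacing))
  phi <- ifelse(mask$values, -(d_out - h), d_in - h)
  array(phi, dims)
}

#' Initialize a level-set state from a mask
#'
#' @param init_mask A nonempty [pet_mask()].
#' @return An object of class `levelset_state` with elements `phi` (signed
#'   distance, negative inside), `spacing`, `iteration` and `front_change`.
#' @export
init_phi <- function(init_mask) {
  stopifnot(inherits(init_mask, "pet_mask"))
  if (!any(init_mask$values)) stop("empty initial mask", call. = FALSE)
  structure(list(phi = signed_distance(init_mask),
                 spacing = init_mask$spacing,
                 iteration = 0L, front_change = NA_real_),
            class = "levelset_state")
}

# Central-difference gradient magnitude in image units per mm.
gradient_magnitude <- function(img) {
  v <- img$values
  d <- dim(v)
  g2 <- array(0, d)
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2) next
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * img$spacing[axis]
    if (axis == 1) dv <- (v[ip, , , drop = FALSE] - v[im, , , drop = FALSE]) /
        denom
    else if (axis == 2) dv <- aperm(aperm(v, c(2, 1, 3))[ip, , , drop = FALSE] -
        aperm(v, c(2, 1, 3))[im, , , drop = FALSE], c(2, 1, 3)) / rep(denom, each = d[1])
    else dv <- aperm(aperm(v, c(3, 2, 1))[ip, , , drop = FALSE] -
        aperm(v, c(3, 2, 1))[im, , , drop = FALSE], c(3, 2, 1)) /
        rep(denom, each = d[1] * d[2])
    g2 <- g2 + dv^2
  }
  sqrt(g2)
}

edge_stopping <- function(img, lambda = NULL) {
  gm <- gradient_magnitude(img)
  if (is.null(lambda)) {
    nz <- gm[gm > 0]
    lambda <- if (length(nz)) stats::median(nz) else 1
  }
  1 / (1 + (gm / lambda)^2)
}

#' One explicit level-set evolution step
#'
#' Updates `phi <- phi + dt * g * (nu - eps * kappa) * |grad phi|` with the
#' balloon term upwinded (Godunov) and the curvature term central, and
#' reinitializes phi to a signed distance every `reinit_every` steps. A step
#' moving any voxel's phi by more than one voxel raises a CFL error.
#'
#' @param img A [pet_volume()] (used for the edge-stopping field; the field
#'   is cached inside `state` after the first call).
#' @param state A `levelset_state` from [init_phi()].
#' @param params A [levelset_params()].
#' @return The updated `levelset_state`.
#' @export
evolve_levelset <- function(img, state, params = levelset_params()) {
  stopifnot(inherits(state, "levelset_state"))
  if (is.null(state$g))
    state$g <- edge_stopping(img, params$lambda)
  h <- min(state$spacing)
  dt <- params$time_step
  if (is.null(dt)) {
    # CFL-safe: advective bound h/|nu| and parabolic bound h^2/(6 eps)
    # (curvature is clamped to 1/h in the stencil)
    dt_adv <- if (abs(params$balloon) > 0) h / abs(params$balloon) else Inf
    dt_par <- if (params$curvature > 0) h^2 / (6 * params$curvature) else Inf
    dt <- 0.3 * min(dt_adv, dt_par, h)
  }
  res <- cpp_levelset_step(state$phi, state$g, dim(state$phi), state$spacing,
                           params$balloon, params$curvature, dt)
  if (res$max_update > h)
    stop("CFL violation: level-set update exceeded one voxel; reduce time_step",
         call. = FALSE)
  state$phi <- res$phi
  state$iteration <- state$iteration + 1L
  state$front_change <- res$flipped / length(state$phi)
  if (state$iteration %% params$reinit_every == 0L && any(res$phi < 0)) {
    state$phi <- signed_distance(pet_mask(res$phi < 0, state$spacing))
  }
  state
}

#' Level-set active-contour segmentation
#'
#' Evolves an initial contour (by default the 40% SUVmax mask, keeping the
#' pipeline automatic) under curvature and balloon forces modulated by the
#' edge-stopping function, until the flipped-voxel fraction stays below
#' `convergence_tol` for 5 consecutive steps or `max_iterations` is
#' reached. The segmentation is `{phi < 0}`.
#'
#' @param img A [pet_volume()] (typically preprocessed).
#' @param seed_point Voxel index used to build the default initialization.
#' @param init_mask Optional nonempty [pet_mask()] overriding the default
#'   40% SUVmax initialization.
#' @param params A [levelset_params()].
#' @param region Optional search-region [pet_mask()] for the default
#'   initialization.
#' @return A [pet_mask()]; empty if the front vanished. A front touching
#'   the image border triggers a warning diagnostic.
#' @export
segment_levelset <- function(img, seed_point = NULL, init_mask = NULL,
                             params = levelset_params(), region = NULL) {
  if (is.null(init_mask)) {
    if (is.null(seed_point))
      stop("either `seed_point` or `init_mask` is required", call. = FALSE)
    init_mask <- segment_pct_max(img, seed_point, 0.40, region)$mask
  }
  if (!any(init_mask$values)) stop("empty initial mask", call. = FALSE)
  state <- init_phi(init_mask)
  quiet <- 0L
  for (it in seq_len(params$max_iterations)) {
    state <- evolve_levelset(img, state, params)
    if (!any(state$phi < 0)) {
      return(pet_mask(array(FALSE, dim(state$phi)), img$spacing))
    }
    quiet <- if (state$front_change < params$convergence_tol) quiet + 1L else 0L
    if (quiet >= 5L) break
  }
  mask <- state$phi < 0
  d <- dim(mask)
  if (any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
      any(mask[, , c(1, d[3])]))
    warning("level-set front reached the image border", call. = FALSE)
  pet_mask(mask, img$spacing)
}
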