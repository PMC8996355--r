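# Synthetic fixtures: labeled "brain-like" phantoms (nested ellipsoidal
# shells with distinct intensities, optional blur and noise) and random
# smooth diffeomorphic warps with a guaranteed positive Jacobian. They make
# every stage of the registration pipeline testable without any image
# downloads; they emulate piecewise-homogeneous skull-stripped anatomy, not
# MR physics.

#' Generate a labeled ellipsoidal-shell phantom
#'
#' Builds a 3-d image of `n_shells` nested ellipsoids with per-seed random
#' center, orientation and semi-axes (inter-subject variability), assigns a
#' distinct intensity to each shell, then optionally blurs and adds
#' Gaussian noise. The matching integer label map (0 = background,
#' innermost shell = highest label) is returned alongside.
#'
#' @param shape integer vector of 3 dimensions (each >= 16).
#' @param n_shells number of nested shells.
#' @param intensity_levels intensities of shells 1 (outermost) to
#'   `n_shells`; default alternates bright/dark for contrast.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param blur_sigma Gaussian blur in voxels (0 = piecewise constant).
#' @param seed integer seed; output is deterministic given the arguments.
#' @return list with `image` (3-d array), `labels` (integer 3-d array) and
#'   `geometry` (center, rotation, per-shell semi-axes) so membership can
#'   be recomputed independently.
#' @export
make_phantom <- function(shape = c(32L, 32L, 32L), n_shells = 3L,
                         intensity_levels = NULL, noise_sd = 0.02,
                         blur_sigma = 1, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape must be 3 integers, each >= 16", call. = FALSE)
  n_shells <- as.integer(n_shells)
  if (is.null(intensity_levels))
    intensity_levels <- (seq_len(n_shells) %% 2) * 0.5 + 0.4 +
      0.05 * seq_len(n_shells)
  if (length(intensity_levels) != n_shells ||
      anyDuplicated(intensity_levels))
    stop("need n_shells distinct intensity levels", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  center <- (shape - 1) / 2 + runif(3, -1, 1) * shape / 16
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M); R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  semi_outer <- shape * 0.38 * runif(3, 0.8, 1)
  fracs <- 1 - 0.55 * (seq_len(n_shells) - 1) / max(n_shells, 2)
  semi <- lapply(fracs, function(f) semi_outer * f)
  g <- expand.grid(x = seq_len(shape[1]) - 1, y = seq_len(shape[2]) - 1,
                   z = seq_len(shape[3]) - 1)
  rel <- t(R) %*% rbind(g$x - center[1], g$y - center[2], g$z - center[3])
  labels <- integer(nrow(g))
  for (k in seq_len(n_shells)) {
    r2 <- (rel[1, ] / semi[[k]][1])^2 + (rel[2, ] / semi[[k]][2])^2 +
      (rel[3, ] / semi[[k]][3])^2
    labels[r2 <= 1] <- k
  }
  labels <- array(labels, dim = shape)
  img <- array(0, dim = shape)
  for (k in seq_len(n_shells)) img[labels == k] <- intensity_levels[k]
  if (blur_sigma > 0) {
    ks <- 2L * as.integer(ceiling(3 * blur_sigma)) + 1L
    ker <- .gauss_kernel(blur_sigma, ks)
    img <- .vol_ext(cpp_sepconv3(.vol_int(img), ker, FALSE))
  }
  if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
  list(image = img, labels = labels,
       geometry = list(center = center, rotation = R, semi_axes = semi))
}

#' Generate a random smooth diffeomorphic velocity field
#'
#' Per-channel white noise is Gaussian-smoothed with `smoothness_sigma`
#' voxels and rescaled so the maximum voxel displacement-rate norm equals
#' `amplitude`. The field is regenerated (with a derived sub-seed) until
#' its scaling-and-squaring integration has a strictly positive minimum
#' Jacobian determinant, so the induced warp is a diffeomorphism by
#' construction.
#'
#' @param shape integer vector of 3 grid dimensions.
#' @param amplitude target maximum velocity norm in voxels (> 0).
#' @param smoothness_sigma Gaussian smoothing of the noise, voxels.
#' @param seed integer seed.
#' @param steps integration steps used for the positivity check.
#' @param max_tries regeneration attempts before giving up.
#' @return velocity field, 4-d array `(shape, 3)`.
#' @export
make_random_svf <- function(shape, amplitude, smoothness_sigma = 4,
                            seed = 1L, steps = 7L, max_tries = 10L) {
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  shape <- as.integer(shape)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  ks <- 2L * as.integer(ceiling(3 * smoothness_sigma)) + 1L
  ker <- .gauss_kernel(smoothness_sigma, ks)
  pad <- as.integer(ceiling(3 * smoothness_sigma))
  big <- shape + 2L * pad
  for (try in seq_len(max_tries)) {
    set.seed(seed + 7919L * (try - 1L))
    # smooth on a padded grid and crop, so the field statistics are
    # stationary (no boundary variance artifacts from border handling)
    v <- array(rnorm(3 * prod(big)), dim = c(3L, big))
    v <- cpp_sepconv3(v, ker, FALSE)
    v <- v[, pad + seq_len(shape[1]), pad + seq_len(shape[2]),
           pad + seq_len(shape[3]), drop = FALSE]
    nrm <- sqrt(v[1L, , , ]^2 + v[2L, , , ]^2 + v[3L, , , ]^2)
    v <- v * (amplitude / max(nrm))
    u <- .int_integrate(v, as.integer(steps))$u
    if (min(cpp_jacdet(u)) > 0) return(.as_field_ext(v))
  }
  stop(sprintf(
    "could not generate a fold-free warp in %d tries; amplitude %.2f is too large for smoothness %.2f",
    max_tries, amplitude, smoothness_sigma), call. = FALSE)
}

#' Generate a registration test pair with known ground-truth warp
#'
#' Creates a phantom as the fixed image, draws a random diffeomorphic
#' velocity field, and produces the moving image (and moving labels, by
#' nearest-neighbour warping) by warping the fixed image with the
#' integrated field. The ground-truth velocity field is returned for
#' recovery and round-trip experiments.
#'
#' @param shape grid dimensions.
#' @param amplitude maximum warp velocity, voxels.
#' @param smoothness_sigma warp smoothness, voxels.
#' @param n_shells,noise_sd,blur_sigma phantom parameters, see
#'   [make_phantom()].
#' @param seed integer seed (phantom and warp use derived sub-seeds).
#' @return list with `fixed`, `moving` (3-d arrays), `labels_fixed`,
#'   `labels_moving` (integer arrays), `gt_svf` (4-d array) and `gt_disp`
#'   (its integration).
#' @export
make_pair <- function(shape = c(48L, 48L, 48L), amplitude = 4,
                      smoothness_sigma = 6, n_shells = 3L, noise_sd = 0.02,
                      blur_sigma = 1, seed = 1L) {
  ph <- make_phantom(shape, n_shells = n_shells, noise_sd = noise_sd,
                     blur_sigma = blur_sigma, seed = seed)
  if (amplitude > 0) {
    gt <- make_random_svf(shape, amplitude, smoothness_sigma,
                          seed = seed + 1000L)
    disp <- integrate_svf(gt, 7L)
  } else {
    gt <- array(0, dim = c(shape, 3L))
    disp <- gt
  }
  moving <- warp_volume(ph$image, disp, "trilinear")
  labels_moving <- warp_volume(ph$labels, disp, "nearest")
  storage.mode(labels_moving) <- "integer"
  list(fixed = ph$image, moving = moving, labels_fixed = ph$labels,
       labels_moving = labels_moving, gt_svf = gt, gt_disp = disp)
}
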