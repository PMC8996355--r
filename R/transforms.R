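# Geometric primitives: image pyramids, stationary-velocity-field (SVF)
# integration by scaling and squaring, warping, composition, in-graph
# Gaussian smoothing, and Jacobian determinants. The exported functions take
# and return the public array representations (see arrays.R); the .int_*
# functions below them are the channel-first internal forms, each paired
# with an analytic backward pass used by the training engine.

#' Multi-resolution image pyramid by recursive average pooling
#'
#' Builds an `levels`-element pyramid by recursively applying 3x3x3
#' average pooling with stride 2 (1-voxel replicate border), so each level
#' has half the dimensions of the next finer one. Element `levels` is the
#' original volume; element 1 is the coarsest.
#'
#' @param vol 3-d numeric array.
#' @param levels integer number of pyramid levels (>= 1).
#' @return list of 3-d arrays, coarsest first, original last.
#' @export
build_pyramid <- function(vol, levels) {
  if (!is.numeric(levels) || length(levels) != 1L || levels < 1)
    stop("levels must be a single integer >= 1", call. = FALSE)
  levels <- as.integer(levels)
  if (length(dim(vol)) != 3L) stop("vol must be a 3-d array", call. = FALSE)
  .check_finite(vol, "vol")
  pyr <- vector("list", levels)
  pyr[[levels]] <- vol
  cur <- vol
  if (levels > 1L) for (l in seq.int(levels - 1L, 1L)) {
    cur <- cpp_avgpool3(cur)
    pyr[[l]] <- cur
  }
  pyr
}

#' Integrate a stationary velocity field by scaling and squaring
#'
#' Computes the displacement field of the time-1 flow of `v`: the field is
#' divided by `2^steps`, then self-composed `steps` times. Seven steps is
#' the default throughout the registration model.
#'
#' @param v velocity field, 4-d array `(n1, n2, n3, 3)` in voxel units of
#'   its own grid.
#' @param steps integer number of squaring steps (>= 1).
#' @return displacement field `u`, same shape, with the map `x -> x + u(x)`.
#' @export
integrate_svf <- function(v, steps = 7L) {
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1)
    stop("steps must be a single integer >= 1", call. = FALSE)
  vi <- .as_field_int(v)
  .check_finite(vi, "v")
  .as_field_ext(.int_integrate(vi, as.integer(steps))$u)
}

#' Compose two displacement fields
#'
#' Returns the displacement `r` of the composed map, i.e.
#' `x + r(x) = (x + inner(x)) + outer(x + inner(x))`, with `outer` sampled
#' by trilinear interpolation and border clamping.
#'
#' @param outer,inner displacement fields, 4-d arrays `(n1, n2, n3, 3)` on
#'   the same grid.
#' @return composed displacement field, same shape.
#' @export
compose_displacements <- function(outer, inner) {
  oi <- .as_field_int(outer); ii <- .as_field_int(inner)
  if (!identical(dim(oi), dim(ii)))
    stop("outer and inner must share the same grid", call. = FALSE)
  .as_field_ext(.int_compose(oi, ii))
}

#' Warp a volume or label map by a displacement field
#'
#' `out(x) = vol(x + u(x))`, sampled with trilinear interpolation for
#' intensity images or nearest neighbour for label maps; out-of-bounds
#' coordinates are clamped to the border.
#'
#' @param vol 3-d numeric array.
#' @param u displacement field `(n1, n2, n3, 3)` on the grid of `vol`, in
#'   voxel units.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return warped 3-d array.
#' @export
warp_volume <- function(vol, u, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  ui <- .as_field_int(u)
  if (!identical(dim(ui)[-1L], dim(vol)))
    stop("displacement grid must match the volume shape", call. = FALSE)
  vi <- .vol_int(vol)
  out <- if (mode == "trilinear") cpp_sample_trilinear(vi, ui)
         else cpp_sample_nearest(vi, ui)
  .vol_ext(out)
}

#' Upsample a vector field onto a finer grid
#'
#' Channel-wise trilinear interpolation with corner-aligned grids. Vector
#' values are not rescaled: velocity fields are stored in full-resolution
#' voxel units at every level, so accumulation across levels after
#' upsampling is plain addition.
#'
#' @param f 4-d array `(n1, n2, n3, 3)`.
#' @param target_shape integer vector of 3 target dimensions, each at least
#'   the source dimension.
#' @return 4-d array `(target_shape, 3)`.
#' @export
upsample_field <- function(f, target_shape) {
  fi <- .as_field_int(f)
  src <- dim(fi)[-1L]
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < src))
    stop("target_shape must be 3 integers, each >= the source dimension",
         call. = FALSE)
  .as_field_ext(cpp_resize_trilinear(fi, target_shape))
}

#' Gaussian smoothing layer for displacement fields
#'
#' Convolves each displacement component with a separable truncated Gaussian
#' kernel (renormalized to sum 1 per axis) using replicate borders. The
#' defaults, sigma 1.732 voxels with a 3x3x3 kernel, are the smoothing-layer
#' setting of the registration model.
#'
#' @param u displacement field `(n1, n2, n3, 3)`.
#' @param sigma Gaussian standard deviation in voxels (> 0).
#' @param ksize odd kernel size.
#' @return smoothed field, same shape.
#' @export
gaussian_smooth_field <- function(u, sigma = 1.732, ksize = 3L) {
  ker <- .gauss_kernel(sigma, ksize)
  .as_field_ext(cpp_sepconv3(.as_field_int(u), ker, FALSE))
}

#' Jacobian determinant of a deformation
#'
#' Per-voxel determinant of `d(x + u(x))/dx`, with central differences in
#' the interior and one-sided differences on the faces; the identity map
#' yields 1 everywhere. Voxels with non-positive values mark folds.
#'
#' @param u displacement field `(n1, n2, n3, 3)` in voxel units.
#' @return 3-d array of determinants.
#' @export
jacobian_determinant <- function(u) {
  ui <- .as_field_int(u)
  if (any(dim(ui)[-1L] < 3L))
    stop("grid must be at least 3 voxels per axis", call. = FALSE)
  cpp_jacdet(ui)
}

#' Reference Euler integration of an SVF flow
#'
#' Slow fixed-step explicit Euler integration of the flow ODE
#' `dD/dt = v(D(t))` from 0 to 1, implemented in plain vectorized R with its
#' own trilinear interpolation. It serves as an independent numerical
#' reference for [integrate_svf()]; it is far too slow for use inside the
#' registration model.
#'
#' @param v velocity field `(n1, n2, n3, 3)` in voxel units of its grid.
#' @param steps number of uniform Euler steps.
#' @return displacement field, same shape.
#' @export
svf_flow_euler <- function(v, steps = 1024L) {
  d <- dim(v)
  if (length(d) != 4L || d[4] != 3L)
    stop("v must be a 4-d array (n1, n2, n3, 3)", call. = FALSE)
  n <- d[1:3]
  vx <- v[, , , 1L]; vy <- v[, , , 2L]; vz <- v[, , , 3L]
  g <- expand.grid(x = seq_len(n[1]) - 1, y = seq_len(n[2]) - 1,
                   z = seq_len(n[3]) - 1)
  px <- g$x; py <- g$y; pz <- g$z
  interp <- function(a, qx, qy, qz) {
    qx <- pmin(pmax(qx, 0), n[1] - 1)
    qy <- pmin(pmax(qy, 0), n[2] - 1)
    qz <- pmin(pmax(qz, 0), n[3] - 1)
    i0 <- pmin(floor(qx), n[1] - 2); j0 <- pmin(floor(qy), n[2] - 2)
    k0 <- pmin(floor(qz), n[3] - 2)
    fx <- qx - i0; fy <- qy - j0; fz <- qz - k0
    at <- function(ii, jj, kk) a[1 + ii + n[1] * (jj + n[2] * kk)]
    (1 - fx) * (1 - fy) * (1 - fz) * at(i0, j0, k0) +
      fx * (1 - fy) * (1 - fz) * at(i0 + 1, j0, k0) +
      (1 - fx) * fy * (1 - fz) * at(i0, j0 + 1, k0) +
      fx * fy * (1 - fz) * at(i0 + 1, j0 + 1, k0) +
      (1 - fx) * (1 - fy) * fz * at(i0, j0, k0 + 1) +
      fx * (1 - fy) * fz * at(i0 + 1, j0, k0 + 1) +
      (1 - fx) * fy * fz * at(i0, j0 + 1, k0 + 1) +
      fx * fy * fz * at(i0 + 1, j0 + 1, k0 + 1)
  }
  h <- 1 / steps
  for (s in seq_len(steps)) {
    px1 <- px + h * interp(vx, px, py, pz)
    py1 <- py + h * interp(vy, px, py, pz)
    pz1 <- pz + h * interp(vz, px, py, pz)
    px <- px1; py <- py1; pz <- pz1
  }
  u <- array(0, dim = d)
  u[, , , 1L] <- array(px - g$x, dim = n)
  u[, , , 2L] <- array(py - g$y, dim = n)
  u[, , , 3L] <- array(pz - g$z, dim = n)
  u
}

# ---- internal channel-first forms with backward passes ----------------------

.int_compose <- function(outer, inner) {
  inner + cpp_sample_trilinear(outer, inner)
}

.int_compose_bw <- function(outer, inner, g) {
  s <- cpp_sample_trilinear_bw(outer, inner, g)
  list(gouter = s$gx, ginner = g + s$gdisp)
}

.int_integrate <- function(v, steps) cpp_integrate(v, steps)

.int_integrate_bw <- function(ic, gu) cpp_integrate_bw(ic, gu)

.gauss_kernel <- function(sigma, ksize) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  ksize <- as.integer(ksize)
  if (ksize %% 2L == 0L) stop("ksize must be odd", call. = FALSE)
  r <- (ksize - 1L) / 2L
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}
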