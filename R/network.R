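# The per-resolution sub-networks regressing incremental stationary
# velocity fields from full-resolution image pairs, and the coarse-to-fine
# multi-resolution forward pass.
#
# Every sub-network shares the encoder: one stride-2 convolution with 16
# filters followed by three stride-2 convolutions with 32 filters (input
# downsampled by 16). The decoder has `level` transposed convolutions with
# 32 filters and stride 2, so sub-networks 1..3 emit fields at 1/8, 1/4 and
# 1/2 of the input resolution, followed by 32- and 16-filter convolutions
# and a 3-channel output convolution. All kernels are 3x3x3; all layers but
# the output use LeakyReLU (slope 0.2). The output convolution is
# zero-initialized so optimization starts from the identity transform.

.LEAKY_SLOPE <- 0.2

.leaky <- function(x) {
  m <- x > 0
  x * (.LEAKY_SLOPE + (1 - .LEAKY_SLOPE) * m)
}
.leaky_bw <- function(pre, g) {
  m <- pre > 0
  g * (.LEAKY_SLOPE + (1 - .LEAKY_SLOPE) * m)
}

.init_w <- function(dims, fan_in, zero = FALSE) {
  w <- if (zero) rep(0, prod(dims))
       else rnorm(prod(dims), sd = sqrt(2 / fan_in))
  array(w, dim = dims)
}

#' Build one velocity-estimation sub-network
#'
#' Constructs the parameter container for the sub-network of a resolution
#' level. Level `l` maps a 2-channel full-resolution input (moving-or-warped
#' image stacked with the fixed image) to a 3-channel stationary velocity
#' field at `1/2^(4-l)` of the input resolution.
#'
#' @param level integer in 1..3 (1 = coarsest, emitting at 1/8 resolution).
#' @return an object of class `mdreg_subnet`: a list with the level and a
#'   list of layer parameter sets.
#' @export
build_subnetwork <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !(level %in% 1:3))
    stop("level must be 1, 2 or 3", call. = FALSE)
  level <- as.integer(level)
  layers <- list()
  enc <- c(2L, 16L, 32L, 32L, 32L)
  for (i in 1:4) {
    ci <- enc[i]; co <- enc[i + 1L]
    layers[[length(layers) + 1L]] <- list(
      type = "conv", stride = 2L, pad = 1L, act = TRUE,
      W = .init_w(c(co, ci, 3L, 3L, 3L), ci * 27),
      b = rep(0, co))
  }
  for (i in seq_len(level)) {
    layers[[length(layers) + 1L]] <- list(
      type = "convt", act = TRUE,
      W = .init_w(c(32L, 32L, 3L, 3L, 3L), 32 * 27),
      b = rep(0, 32L))
  }
  head <- list(c(32L, 32L), c(32L, 16L), c(16L, 3L))
  for (i in 1:3) {
    ci <- head[[i]][1]; co <- head[[i]][2]
    layers[[length(layers) + 1L]] <- list(
      type = "conv", stride = 1L, pad = 1L, act = i < 3L,
      W = .init_w(c(co, ci, 3L, 3L, 3L), ci * 27, zero = i == 3L),
      b = rep(0, co))
  }
  structure(list(level = level, layers = layers), class = "mdreg_subnet")
}

#' @export
print.mdreg_subnet <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("Velocity sub-network, level %d (output at 1/%d resolution)\n",
              x$level, 2^(4 - x$level)))
  cat(sprintf("  %d layers, %d parameters\n", length(x$layers), np))
  invisible(x)
}

.subnet_forward <- function(net, x, want_cache = FALSE) {
  cache <- if (want_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    pre <- if (ly$type == "conv")
      cpp_conv3d(x, ly$W, ly$b, ly$stride, ly$pad)
    else
      cpp_convt3d(x, ly$W, ly$b)
    out <- if (ly$act) .leaky(pre) else pre
    if (want_cache) cache[[i]] <- list(x = x, pre = if (ly$act) pre else NULL)
    x <- out
  }
  list(out = x, cache = cache)
}

.subnet_backward <- function(net, cache, gy) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    if (ly$act) gy <- .leaky_bw(cc$pre, gy)
    bw <- if (ly$type == "conv")
      cpp_conv3d_bw(cc$x, ly$W, gy, ly$stride, ly$pad)
    else
      cpp_convt3d_bw(cc$x, ly$W, gy)
    grads[[i]] <- list(gw = bw$gw, gb = bw$gb)
    gy <- bw$gx
  }
  list(grads = grads, gx = gy)
}

.concat2 <- function(a, b) {
  # stack two (1, n) channel-first volumes into a (2, n) input
  d <- dim(a)[-1L]
  out <- array(0, dim = c(2L, d))
  out[1L, , , ] <- a
  out[2L, , , ] <- b
  out
}

# Coarse-to-fine forward pass (internal). fix/mov are (1, n) arrays on a
# /16-divisible grid. Sub-network 1 sees (moving, fixed); for l > 1 the
# moving image is first warped at full resolution by the integrated,
# upsampled accumulated field of the coarser levels (without the smoothing
# layer, which acts only on the finest-level output). Returns incremental
# and accumulated fields plus the caches needed for backpropagation.
.fm_forward <- function(fix, mov, nets, cfg, want_cache = FALSE) {
  L <- length(nets)
  full_dims <- dim(fix)[-1L]
  v <- vt <- vector("list", L)
  ncache <- icache <- warped_in <- vector("list", L)
  for (l in seq_len(L)) {
    if (l == 1L) {
      xin <- .concat2(mov, fix)
    } else {
      up_prev <- cpp_resize_trilinear(vt[[l - 1L]], full_dims)
      ic <- .int_integrate(up_prev, cfg$steps)
      wm <- cpp_sample_trilinear(mov, ic$u)
      warped_in[[l]] <- wm
      icache[[l]] <- ic
      xin <- .concat2(wm, fix)
    }
    sf <- .subnet_forward(nets[[l]], xin, want_cache)
    v[[l]] <- sf$out
    ncache[[l]] <- sf$cache
    vt[[l]] <- if (l == 1L) v[[1L]]
               else cpp_resize_trilinear(vt[[l - 1L]], dim(v[[l]])[-1L]) + v[[l]]
  }
  list(v = v, vt = vt, ncache = ncache, icache = icache,
       warped_in = warped_in, full_dims = full_dims)
}

# Backward through the coarse-to-fine pass. g_vt_direct / g_tv_direct come
# from the loss (.mr_loss); the accumulation chain and the warped-input
# path of each finer sub-network both feed gradient back to coarser levels.
.fm_backward <- function(fm, nets, mov, g_vt_direct, g_tv_direct, cfg) {
  L <- length(nets)
  g_vt <- g_vt_direct
  pgrads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gv_l <- g_vt[[l]] + g_tv_direct[[l]]
    sb <- .subnet_backward(nets[[l]], fm$ncache[[l]], gv_l)
    pgrads[[l]] <- sb$grads
    if (l > 1L) {
      gl_prev <- dim(fm$v[[l - 1L]])[-1L]
      g_vt[[l - 1L]] <- g_vt[[l - 1L]] +
        cpp_resize_trilinear_bw(g_vt[[l]], gl_prev)
      gwm <- array(0, dim = c(1L, fm$full_dims))
      gwm[1L, , , ] <- sb$gx[1L, , , ]
      gu <- cpp_sample_trilinear_bw(mov, fm$icache[[l]]$u, gwm)$gdisp
      gup <- .int_integrate_bw(fm$icache[[l]], gu)
      g_vt[[l - 1L]] <- g_vt[[l - 1L]] +
        cpp_resize_trilinear_bw(gup, gl_prev)
    }
  }
  pgrads
}

#' Coarse-to-fine multi-resolution forward pass
#'
#' Runs the full multi-resolution estimation on one image pair with the
#' given sub-networks: incremental velocity fields are predicted coarse to
#' fine (the moving image re-warped by the accumulated field before each
#' finer sub-network), accumulated, and the finest accumulated field is
#' upsampled to the full grid, integrated in both directions and passed
#' through the Gaussian smoothing layer to give the final forward and
#' inverse displacement fields.
#'
#' @param fixed,moving 3-d arrays of identical shape (padded internally to
#'   /16-divisible dimensions; outputs are cropped back).
#' @param nets list of `cfg$levels` sub-networks from [build_subnetwork()].
#' @param cfg an [mdreg_config()].
#' @return list with `svfs` (incremental fields, external layout),
#'   `accumulated` (accumulated fields per level), `warped_inputs` (the
#'   warped moving volumes fed to the finer sub-networks),
#'   `forward_field` and `inverse_field` (full-grid displacement fields)
#'   and `warped_moving` (moving warped by the forward field).
#' @export
forward_multires <- function(fixed, moving, nets, cfg = mdreg_config()) {
  if (!identical(dim(fixed), dim(moving)))
    stop("fixed and moving must have identical shape", call. = FALSE)
  pf <- pad_volume(fixed); pm <- pad_volume(moving)
  fix <- .vol_int(pf$data); mov <- .vol_int(pm$data)
  fm <- .fm_forward(fix, mov, nets, cfg, want_cache = FALSE)
  fin <- .final_fields(fm$vt[[length(nets)]], fm$full_dims, cfg)
  wm <- cpp_sample_trilinear(mov, fin$fwd)
  list(svfs = lapply(fm$v, .as_field_ext),
       accumulated = lapply(fm$vt, .as_field_ext),
       warped_inputs = lapply(fm$warped_in,
                              function(w) if (is.null(w)) NULL
                              else .crop3(.vol_ext(w), pm$index)),
       forward_field = .crop_field(.as_field_ext(fin$fwd), pf$index),
       inverse_field = .crop_field(.as_field_ext(fin$inv), pf$index),
       warped_moving = .crop3(.vol_ext(wm), pf$index))
}

# Final full-grid displacement fields from the finest accumulated SVF:
# upsample, integrate +/- (7 steps), smooth at the finest resolution.
.final_fields <- function(vtL, full_dims, cfg) {
  vfull <- cpp_resize_trilinear(vtL, full_dims)
  fwd <- .int_integrate(vfull, cfg$steps)$u
  inv <- .int_integrate(-vfull, cfg$steps)$u
  if (isTRUE(cfg$smooth)) {
    ker <- .gauss_kernel(cfg$sigma, cfg$ksize)
    fwd <- cpp_sepconv3(fwd, ker, FALSE)
    inv <- cpp_sepconv3(inv, ker, FALSE)
  }
  list(fwd = fwd, inv = inv)
}
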