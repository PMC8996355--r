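# Similarity and regularization terms and their multi-resolution,
# bidirectional assembly. Every term used during optimization has an
# analytic gradient (the .*_grad helpers); the exported functions are the
# forward evaluations.

.NCC_EPS <- 1e-5

#' Normalized cross-correlation between two volumes
#'
#' In `"global"` mode, the Pearson correlation of all voxels; in windowed
#' mode (odd integer window size), the mean over voxels of the local
#' zero-normalized cross-correlation within the window (windows are cropped
#' at the volume boundary). A small epsilon (1e-5) is added to the variance
#' product, so constant inputs give 0 instead of a division error.
#'
#' @param a,b 3-d numeric arrays of identical shape.
#' @param window odd integer window size, or `"global"`.
#' @return a scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b, window = 9L) {
  .ncc_check(a, b, window)
  if (identical(window, "global")) .ncc_global(a, b)$value
  else .ncc_local(a, b, as.integer(window))$value
}

.ncc_check <- function(a, b, window) {
  if (!identical(dim(a), dim(b)))
    stop("a and b must have identical shape", call. = FALSE)
  if (!identical(window, "global")) {
    if (!is.numeric(window) || length(window) != 1L || window < 1 ||
        as.integer(window) %% 2L == 0L)
      stop("window must be an odd integer or \"global\"", call. = FALSE)
  }
  invisible(NULL)
}

.ncc_global <- function(a, b, want_grad = FALSE) {
  n <- length(a)
  ac <- a - mean(a); bc <- b - mean(b)
  cv <- sum(ac * bc) / n
  va <- sum(ac * ac) / n
  vb <- sum(bc * bc) / n
  D <- sqrt(va * vb + .NCC_EPS)
  r <- cv / D
  out <- list(value = r)
  if (want_grad) {
    out$ga <- array((bc / D - cv * vb * ac / D^3) / n, dim = dim(a))
    out$gb <- array((ac / D - cv * va * bc / D^3) / n, dim = dim(b))
  }
  out
}

.ncc_local <- function(a, b, w, want_grad = FALSE) {
  dims <- dim(a)
  ones <- array(1, dim = dims)
  cnt <- cpp_boxsum(ones, w)
  sI <- cpp_boxsum(a, w);  sJ <- cpp_boxsum(b, w)
  sII <- cpp_boxsum(a * a, w); sJJ <- cpp_boxsum(b * b, w)
  sIJ <- cpp_boxsum(a * b, w)
  mI <- sI / cnt; mJ <- sJ / cnt
  cross <- sIJ - sI * sJ / cnt
  varI <- pmax(sII - sI * sI / cnt, 0)
  varJ <- pmax(sJJ - sJ * sJ / cnt, 0)
  D <- sqrt(varI * varJ + .NCC_EPS)
  cc <- cross / D
  nv <- length(a)
  out <- list(value = sum(cc) / nv)
  if (want_grad) {
    # d cc_w / d b(y) = (a(y) - mI_w)/D_w - cross_w varI_w (b(y) - mJ_w)/D_w^3
    # summed over windows w containing y via the (self-adjoint) box filter.
    alpha <- 1 / D
    beta <- cross * varI / D^3
    out$gb <- (a * cpp_boxsum(alpha, w) - cpp_boxsum(alpha * mI, w) -
               b * cpp_boxsum(beta, w) + cpp_boxsum(beta * mJ, w)) / nv
    alpha2 <- alpha
    beta2 <- cross * varJ / D^3
    out$ga <- (b * cpp_boxsum(alpha2, w) - cpp_boxsum(alpha2 * mJ, w) -
               a * cpp_boxsum(beta2, w) + cpp_boxsum(beta2 * mI, w)) / nv
  }
  out
}

.ncc_grad <- function(a, b, window) .ncc_eval(a, b, window, TRUE)

.ncc_eval <- function(a, b, window, want_grad = FALSE) {
  if (identical(window, "global")) .ncc_global(a, b, want_grad)
  else .ncc_local(a, b, as.integer(window), want_grad)
}

#' Total-variation regularizer of a velocity field
#'
#' Mean (over voxels) of the summed absolute forward differences of all
#' three components along all three axes, with a zero-gradient (replicate)
#' boundary. Dividing by the voxel count keeps the term on one scale across
#' resolutions, so a single weight applies to every level.
#'
#' @param v 4-d array `(n1, n2, n3, 3)`.
#' @return non-negative scalar.
#' @export
tv_regularizer <- function(v) {
  .tv(.as_field_int(v))$value
}

.tv <- function(vi, want_grad = FALSE) {
  n <- dim(vi)[-1L]
  nv <- prod(n)
  total <- 0
  g <- if (want_grad) array(0, dim = dim(vi)) else NULL
  for (axis in 1:3) {
    na <- n[axis]
    if (na < 2L) next
    hi <- switch(axis,
      vi[, 2:na, , , drop = FALSE],
      vi[, , 2:na, , drop = FALSE],
      vi[, , , 2:na, drop = FALSE])
    lo <- switch(axis,
      vi[, 1:(na - 1L), , , drop = FALSE],
      vi[, , 1:(na - 1L), , drop = FALSE],
      vi[, , , 1:(na - 1L), drop = FALSE])
    d <- hi - lo
    total <- total + sum(abs(d))
    if (want_grad) {
      s <- sign(d) / nv
      if (axis == 1L) {
        g[, 2:na, , ] <- g[, 2:na, , , drop = FALSE] + s
        g[, 1:(na - 1L), , ] <- g[, 1:(na - 1L), , , drop = FALSE] - s
      } else if (axis == 2L) {
        g[, , 2:na, ] <- g[, , 2:na, , drop = FALSE] + s
        g[, , 1:(na - 1L), ] <- g[, , 1:(na - 1L), , drop = FALSE] - s
      } else {
        g[, , , 2:na] <- g[, , , 2:na, drop = FALSE] + s
        g[, , , 1:(na - 1L)] <- g[, , , 1:(na - 1L), drop = FALSE] - s
      }
    }
  }
  list(value = total / nv, grad = g)
}

# ---- multi-resolution bidirectional assembly --------------------------------

# Per-axis factor converting a displacement stored in full-resolution voxel
# units into voxel units of a coarser corner-aligned grid.
.level_scale <- function(level_dims, full_dims) {
  ifelse(full_dims > 1L, (level_dims - 1) / (full_dims - 1), 1)
}

.scale_field <- function(vi, fac) {
  vi[1L, , , ] <- vi[1L, , , ] * fac[1]
  vi[2L, , , ] <- vi[2L, , , ] * fac[2]
  vi[3L, , , ] <- vi[3L, , , ] * fac[3]
  vi
}

# Core forward (and optional backward) of the deep-supervision loss.
#
#  fix_pyr / mov_pyr : lists of internal (1, n) image arrays, coarsest first,
#                      element L+1 = full resolution (length L + 1).
#  v_list            : incremental velocity fields (internal layout), level l
#                      on the grid of pyramid element l, full-res voxel units.
#
# Per level l: accumulate vt_l = resize(vt_{l-1}) + v_l, convert to level
# voxel units, integrate +/- by scaling and squaring, warp the level images
# in both directions and score NCC; the TV penalty applies to the increment
# v_l on its native grid. At the finest (full) resolution the accumulated
# field is upsampled, integrated and passed through the Gaussian smoothing
# layer before the bidirectional full-resolution similarity term.
.mr_loss <- function(fix_pyr, mov_pyr, v_list, cfg, want_grad = FALSE) {
  L <- length(v_list)
  full_dims <- dim(fix_pyr[[L + 1L]])[-1L]
  vt <- vector("list", L)
  sim_f <- sim_i <- tvv <- numeric(0)
  lvl_cache <- vector("list", L)
  tv_res <- vector("list", L)
  for (l in seq_len(L)) {
    gl <- dim(v_list[[l]])[-1L]
    vt[[l]] <- if (l == 1L) v_list[[1L]]
               else cpp_resize_trilinear(vt[[l - 1L]], gl) + v_list[[l]]
    fac <- .level_scale(gl, full_dims)
    ip <- .int_integrate(.scale_field(vt[[l]], fac), cfg$steps)
    im <- .int_integrate(.scale_field(-vt[[l]], fac), cfg$steps)
    wm <- cpp_sample_trilinear(mov_pyr[[l]], ip$u)
    wf <- cpp_sample_trilinear(fix_pyr[[l]], im$u)
    nf <- .ncc_eval(.vol_ext(fix_pyr[[l]]), .vol_ext(wm), cfg$ncc_window,
                    want_grad)
    ni <- .ncc_eval(.vol_ext(mov_pyr[[l]]), .vol_ext(wf), cfg$ncc_window,
                    want_grad)
    sim_f[l] <- nf$value
    sim_i[l] <- ni$value
    # the increment is regularized in its own grid's voxel units (the
    # full-resolution storage units would inflate coarse-level gradients
    # by the grid-spacing ratio)
    tv_res[[l]] <- .tv(.scale_field(v_list[[l]], fac), want_grad)
    tvv[l] <- tv_res[[l]]$value
    lvl_cache[[l]] <- list(ip = ip, im = im, wm = wm, wf = wf, fac = fac,
                           nf = nf, ni = ni)
  }
  full_cache <- NULL
  if (isTRUE(cfg$full_res_sim)) {
    vfull <- cpp_resize_trilinear(vt[[L]], full_dims)
    ipf <- .int_integrate(vfull, cfg$steps)
    imf <- .int_integrate(-vfull, cfg$steps)
    ker <- if (isTRUE(cfg$smooth)) .gauss_kernel(cfg$sigma, cfg$ksize) else NULL
    up <- if (is.null(ker)) ipf$u else cpp_sepconv3(ipf$u, ker, FALSE)
    um <- if (is.null(ker)) imf$u else cpp_sepconv3(imf$u, ker, FALSE)
    wm <- cpp_sample_trilinear(mov_pyr[[L + 1L]], up)
    wf <- cpp_sample_trilinear(fix_pyr[[L + 1L]], um)
    nf <- .ncc_eval(.vol_ext(fix_pyr[[L + 1L]]), .vol_ext(wm),
                    cfg$ncc_window, want_grad)
    ni <- .ncc_eval(.vol_ext(mov_pyr[[L + 1L]]), .vol_ext(wf),
                    cfg$ncc_window, want_grad)
    sim_f[L + 1L] <- nf$value
    sim_i[L + 1L] <- ni$value
    tvv[L + 1L] <- 0
    full_cache <- list(ipf = ipf, imf = imf, ker = ker, up = up, um = um,
                       wm = wm, wf = wf, nf = nf, ni = ni)
  }
  total <- sum(-sim_f - sim_i + cfg$lambda * tvv)
  out <- list(per_level_similarity_fwd = sim_f,
              per_level_similarity_inv = sim_i,
              per_level_tv = tvv, total = total, vt = vt)
  if (!want_grad) return(out)

  # ---- backward: direct gradients w.r.t. each accumulated field vt_l and
  # the TV part w.r.t. each increment v_l. The chain through the
  # accumulation vt_l = resize(vt_{l-1}) + v_l is left to the caller so the
  # warped-input path of the network can inject its own contributions.
  g_vt_direct <- vector("list", L)
  g_tv_direct <- vector("list", L)
  for (l in seq_len(L)) {
    lc <- lvl_cache[[l]]
    # total has -sim terms
    gwm <- .vol_int(-lc$nf$gb)
    gwf <- .vol_int(-lc$ni$gb)
    gu_p <- cpp_sample_trilinear_bw(mov_pyr[[l]], lc$ip$u, gwm)$gdisp
    gu_m <- cpp_sample_trilinear_bw(fix_pyr[[l]], lc$im$u, gwf)$gdisp
    gs_p <- .int_integrate_bw(lc$ip, gu_p)
    gs_m <- .int_integrate_bw(lc$im, gu_m)
    g_vt_direct[[l]] <- .scale_field(gs_p, lc$fac) - .scale_field(gs_m, lc$fac)
    g_tv_direct[[l]] <- cfg$lambda * .scale_field(tv_res[[l]]$grad, lc$fac)
  }
  if (!is.null(full_cache)) {
    fc <- full_cache
    gu_p <- cpp_sample_trilinear_bw(mov_pyr[[L + 1L]], fc$up,
                                    .vol_int(-fc$nf$gb))$gdisp
    gu_m <- cpp_sample_trilinear_bw(fix_pyr[[L + 1L]], fc$um,
                                    .vol_int(-fc$ni$gb))$gdisp
    if (!is.null(fc$ker)) {
      gu_p <- cpp_sepconv3(gu_p, fc$ker, TRUE)
      gu_m <- cpp_sepconv3(gu_m, fc$ker, TRUE)
    }
    gvfull <- .int_integrate_bw(fc$ipf, gu_p) - .int_integrate_bw(fc$imf, gu_m)
    g_vt_direct[[L]] <- g_vt_direct[[L]] +
      cpp_resize_trilinear_bw(gvfull, dim(vt[[L]])[-1L])
  }
  out$g_vt_direct <- g_vt_direct
  out$g_tv_direct <- g_tv_direct
  out
}

# Fold the accumulation chain: gradient w.r.t. each increment v_l alone
# (used by the standalone loss API and its tests; the training engine does
# its own folding because the warped network inputs add extra terms).
.mr_loss_grad_v <- function(res, v_list) {
  L <- length(v_list)
  g_vt <- res$g_vt_direct
  gv <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gv[[l]] <- g_vt[[l]] + res$g_tv_direct[[l]]
    if (l > 1L)
      g_vt[[l - 1L]] <- g_vt[[l - 1L]] +
        cpp_resize_trilinear_bw(g_vt[[l]], dim(v_list[[l - 1L]])[-1L])
  }
  gv
}

#' Multi-resolution bidirectional self-supervision loss
#'
#' Assembles the deep-supervision objective from per-level incremental
#' velocity fields: for each level `l` the increments up to `l` are
#' accumulated (coarser fields upsampled, then added), integrated in both
#' directions by scaling and squaring, and used to warp the level-`l`
#' pyramid images; the negated forward and inverse similarities plus
#' `lambda` times the TV penalty of the increment (expressed in the voxel
#' units of its own grid) are summed over levels.
#' When `cfg$full_res_sim` is `TRUE` an additional full-resolution
#' bidirectional term is computed from the upsampled accumulated field with
#' the Gaussian smoothing layer applied (the in-graph smoothing of the
#' model).
#'
#' @param pyr_f,pyr_m image pyramids from [build_pyramid()] with
#'   `cfg$levels + 1` elements (coarsest first, original last).
#' @param svfs list of `cfg$levels` incremental velocity fields, element `l`
#'   a 4-d array on the grid of pyramid element `l`, in full-resolution
#'   voxel units.
#' @param cfg an [mdreg_config()] object (fields `lambda`, `ncc_window`,
#'   `levels`, `steps`, `sigma`, `ksize`, `full_res_sim`, `smooth`).
#' @return an object of class `mdreg_loss` with the per-level forward and
#'   inverse similarities, per-level TV values and the total.
#' @export
multires_loss <- function(pyr_f, pyr_m, svfs, cfg = mdreg_config()) {
  L <- cfg$levels
  if (length(svfs) != L)
    stop("need exactly cfg$levels incremental velocity fields", call. = FALSE)
  if (length(pyr_f) < L + 1L || length(pyr_m) < L + 1L)
    stop("pyramids must have cfg$levels + 1 elements", call. = FALSE)
  fp <- lapply(pyr_f[seq_len(L + 1L)], .vol_int)
  mp <- lapply(pyr_m[seq_len(L + 1L)], .vol_int)
  vi <- lapply(svfs, .as_field_int)
  for (l in seq_len(L)) {
    if (!identical(dim(vi[[l]])[-1L], dim(fp[[l]])[-1L]))
      stop(sprintf("svfs[[%d]] grid does not match pyramid level %d", l, l),
           call. = FALSE)
  }
  res <- .mr_loss(fp, mp, vi, cfg, want_grad = FALSE)
  structure(res[c("per_level_similarity_fwd", "per_level_similarity_inv",
                  "per_level_tv", "total")],
            class = "mdreg_loss")
}

#' @export
print.mdreg_loss <- function(x, ...) {
  cat("Multi-resolution registration loss\n")
  lv <- seq_along(x$per_level_similarity_fwd)
  for (l in lv) {
    lab <- if (l == length(lv) && length(lv) > 1 &&
               x$per_level_tv[l] == 0) "full" else as.character(l)
    cat(sprintf("  level %-4s sim(fwd) %8.5f  sim(inv) %8.5f  tv %10.6f\n",
                lab, x$per_level_similarity_fwd[l],
                x$per_level_similarity_inv[l], x$per_level_tv[l]))
  }
  cat(sprintf("  total %.6f\n", x$total))
  invisible(x)
}
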