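#' Configuration for the registration model
#'
#' Collects the loss and optimization settings shared by [mdreg()],
#' [mdreg_train()] and [multires_loss()].
#'
#' @param lambda non-negative regularization weight balancing image
#'   similarity against the total-variation penalty on the incremental
#'   velocity fields. The default 0.35 is the value at which validation Dice
#'   peaks while deformations stay fold-free in the full-scale model.
#' @param levels number of resolution levels; 3 means velocity fields at
#'   1/8, 1/4 and 1/2 of the (padded) input resolution.
#' @param steps scaling-and-squaring time steps used for every integration
#'   (default 7).
#' @param sigma,ksize Gaussian smoothing-layer standard deviation (voxels)
#'   and odd kernel size applied to the finest-resolution deformation
#'   (defaults 1.732 and 3).
#' @param ncc_window odd window size of the local normalized
#'   cross-correlation similarity, or `"global"` for the plain Pearson
#'   correlation of all voxels.
#' @param full_res_sim also score the bidirectional similarity at full
#'   resolution using the upsampled, smoothed deformation (this is the term
#'   through which the smoothing layer participates in training).
#' @param smooth enable the Gaussian smoothing layer (disable for ablation
#'   experiments).
#' @param learning_rate Adam step size. The default 1e-4 matches the
#'   full-scale population training; per-pair instance optimization uses
#'   1e-3 unless overridden (hundreds rather than many thousands of
#'   iterations).
#' @param iterations number of optimization iterations.
#' @param batch_size pairs per update (the model is trained with 1).
#' @param seed integer seed making initialization, pair sampling and hence
#'   the whole optimization deterministic.
#' @return an object of class `mdreg_config` (a named list).
#' @export
mdreg_config <- function(lambda = 0.35, levels = 3L, steps = 7L,
                         sigma = 1.732, ksize = 3L, ncc_window = 9L,
                         full_res_sim = TRUE, smooth = TRUE,
                         learning_rate = 1e-4, iterations = 150000L,
                         batch_size = 1L, seed = 1L) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (steps < 1L) stop("steps must be >= 1", call. = FALSE)
  if (iterations < 0L) stop("iterations must be >= 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (!identical(ncc_window, "global")) {
    ncc_window <- as.integer(ncc_window)
    if (ncc_window %% 2L == 0L)
      stop("ncc_window must be odd or \"global\"", call. = FALSE)
  }
  structure(list(lambda = lambda, levels = as.integer(levels),
                 steps = as.integer(steps), sigma = sigma,
                 ksize = as.integer(ksize), ncc_window = ncc_window,
                 full_res_sim = isTRUE(full_res_sim),
                 smooth = isTRUE(smooth),
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "mdreg_config")
}

#' @export
print.mdreg_config <- function(x, ...) {
  cat("mdreg configuration\n")
  cat(sprintf("  levels %d, steps %d, lambda %g, ncc_window %s\n",
              x$levels, x$steps, x$lambda, as.character(x$ncc_window)))
  cat(sprintf("  smoothing layer: %s (sigma %g, ksize %d), full-res term: %s\n",
              if (x$smooth) "on" else "off", x$sigma, x$ksize,
              if (x$full_res_sim) "on" else "off"))
  cat(sprintf("  Adam lr %g, batch %d, iterations %d, seed %d\n",
              x$learning_rate, x$batch_size, x$iterations, x$seed))
  invisible(x)
}
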