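# Self-supervised optimization: Adam over the sub-network parameters,
# driven by the multi-resolution bidirectional loss. Used in two modes:
# population training over a stream of image pairs (mdreg_train) and
# per-pair instance optimization (mdreg with mode = "instance"), which is
# conventional iterative registration with a network-parameterized
# transform.

# ---- parameter flattening / Adam --------------------------------------------

.param_walk <- function(nets, fn) {
  for (l in seq_along(nets))
    for (i in seq_along(nets[[l]]$layers))
      fn(l, i)
  invisible(NULL)
}

.adam_init <- function(nets) {
  st <- list(t = 0L, m = list(), v = list())
  for (l in seq_along(nets)) {
    st$m[[l]] <- st$v[[l]] <- vector("list", length(nets[[l]]$layers))
    for (i in seq_along(nets[[l]]$layers)) {
      ly <- nets[[l]]$layers[[i]]
      st$m[[l]][[i]] <- list(W = array(0, dim = dim(ly$W)),
                             b = rep(0, length(ly$b)))
      st$v[[l]][[i]] <- list(W = array(0, dim = dim(ly$W)),
                             b = rep(0, length(ly$b)))
    }
  }
  st
}

.adam_step <- function(nets, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (l in seq_along(nets)) {
    for (i in seq_along(nets[[l]]$layers)) {
      g <- grads[[l]][[i]]
      for (p in c("W", "b")) {
        gp <- if (p == "W") g$gw else g$gb
        st$m[[l]][[i]][[p]] <- beta1 * st$m[[l]][[i]][[p]] + (1 - beta1) * gp
        st$v[[l]][[i]][[p]] <- beta2 * st$v[[l]][[i]][[p]] + (1 - beta2) * gp^2
        mhat <- st$m[[l]][[i]][[p]] / bc1
        vhat <- st$v[[l]][[i]][[p]] / bc2
        nets[[l]]$layers[[i]][[p]] <- nets[[l]]$layers[[i]][[p]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(nets = nets, st = st)
}

# ---- one optimization step on one (padded, normalized) pair -----------------

.loss_step <- function(nets, fix, mov, pyr_f, pyr_m, cfg) {
  fm <- .fm_forward(fix, mov, nets, cfg, want_cache = TRUE)
  ml <- .mr_loss(pyr_f, pyr_m, fm$v, cfg, want_grad = TRUE)
  if (!is.finite(ml$total)) {
    bad <- c(fwd = any(!is.finite(ml$per_level_similarity_fwd)),
             inv = any(!is.finite(ml$per_level_similarity_inv)),
             tv = any(!is.finite(ml$per_level_tv)))
    stop(sprintf(
      "non-finite loss (offending terms: %s); try a smaller learning rate",
      paste(names(bad)[bad], collapse = ", ")), call. = FALSE)
  }
  pgrads <- .fm_backward(fm, nets, mov, ml$g_vt_direct, ml$g_tv_direct, cfg)
  list(loss = ml, grads = pgrads, fm = fm)
}

.prep_pair <- function(fixed, moving) {
  pf <- pad_volume(.normalize01(fixed))
  pm <- pad_volume(.normalize01(moving))
  list(fix = .vol_int(pf$data), mov = .vol_int(pm$data), index = pf$index)
}

.pair_pyramids <- function(fix, mov, levels) {
  list(pf = lapply(build_pyramid(.vol_ext(fix), levels + 1L), .vol_int),
       pm = lapply(build_pyramid(.vol_ext(mov), levels + 1L), .vol_int))
}

.breakdown_row <- function(iter, ml) {
  L <- length(ml$per_level_similarity_fwd)
  row <- c(iteration = iter,
           setNames(ml$per_level_similarity_fwd, paste0("sim_fwd_", seq_len(L))),
           setNames(ml$per_level_similarity_inv, paste0("sim_inv_", seq_len(L))),
           setNames(ml$per_level_tv, paste0("tv_", seq_len(L))),
           total = ml$total)
  as.data.frame(as.list(row))
}

# ---- pair sampling ----------------------------------------------------------

#' Sample ordered training pairs from an image set
#'
#' Draws uniformly at random from all `n^2` ordered (fixed, moving) pairs of
#' `n` images, self-pairs included, so every image can serve as the fixed
#' image. Reproducible under `seed`.
#'
#' @param ids vector of image identifiers (length >= 1).
#' @param n_pairs number of draws.
#' @param seed integer seed.
#' @return data.frame with columns `fixed` and `moving`.
#' @export
sample_pairs <- function(ids, n_pairs, seed = 1L) {
  if (length(ids) < 1L) stop("empty dataset", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fi <- sample.int(length(ids), n_pairs, replace = TRUE)
  mi <- sample.int(length(ids), n_pairs, replace = TRUE)
  data.frame(fixed = ids[fi], moving = ids[mi], stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# ---- population training ----------------------------------------------------

#' Train a registration model on a set of volumes
#'
#' Self-supervised pairwise training: at each iteration a (fixed, moving)
#' pair is drawn uniformly from all ordered pairs of `volumes` (self-pairs
#' included), the multi-resolution bidirectional loss is evaluated and all
#' sub-networks are updated jointly by one Adam step. Fully deterministic
#' under `cfg$seed`.
#'
#' @param volumes list of 3-d arrays of identical shape.
#' @param cfg an [mdreg_config()]; `cfg$iterations` controls the length of
#'   the run and `cfg$learning_rate` the Adam step size.
#' @param log_path optional CSV path receiving the per-iteration loss
#'   breakdown.
#' @return an object of class `mdreg_model`: the trained sub-networks, the
#'   configuration and the loss trace (data.frame).
#' @export
mdreg_train <- function(volumes, cfg = mdreg_config(), log_path = NULL) {
  if (length(volumes) < 1L) stop("empty dataset", call. = FALSE)
  shp <- dim(volumes[[1L]])
  for (v in volumes) if (!identical(dim(v), shp))
    stop("all volumes must share one shape", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  nets <- lapply(seq_len(cfg$levels), function(l) build_subnetwork(l))
  st <- .adam_init(nets)
  prepped <- lapply(volumes, function(v) .prep_pair(v, v)$fix)
  pyrs <- lapply(prepped, function(p)
    lapply(build_pyramid(.vol_ext(p), cfg$levels + 1L), .vol_int))
  pairs <- data.frame(
    fixed = sample.int(length(volumes), cfg$iterations, replace = TRUE),
    moving = sample.int(length(volumes), cfg$iterations, replace = TRUE))
  trace <- vector("list", cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    fi <- pairs$fixed[it]; mi <- pairs$moving[it]
    stp <- .loss_step(nets, prepped[[fi]], prepped[[mi]],
                      pyrs[[fi]], pyrs[[mi]], cfg)
    upd <- .adam_step(nets, stp$grads, st, cfg$learning_rate)
    nets <- upd$nets; st <- upd$st
    trace[[it]] <- .breakdown_row(it, stp$loss)
  }
  trace <- do.call(rbind, trace)
  if (!is.null(log_path)) write.csv(trace, log_path, row.names = FALSE)
  structure(list(nets = nets, config = cfg, loss_trace = trace,
                 input_shape = shp, pairs = pairs),
            class = "mdreg_model")
}

#' @export
print.mdreg_model <- function(x, ...) {
  cat(sprintf("Trained multi-resolution registration model (%d levels)\n",
              x$config$levels))
  cat(sprintf("  input shape %s, %d iterations, lambda %g\n",
              paste(x$input_shape, collapse = "x"),
              nrow(x$loss_trace), x$config$lambda))
  if (nrow(x$loss_trace) > 0)
    cat(sprintf("  loss: first %.4f, last %.4f\n",
                x$loss_trace$total[1L],
                x$loss_trace$total[nrow(x$loss_trace)]))
  invisible(x)
}
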