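# Array plumbing shared by all modules.
#
# Public representation: scalar volumes are 3-d numeric arrays; vector
# (velocity / displacement) fields are 4-d arrays dim c(n1, n2, n3, 3) with
# the displacement components in the last margin, in voxel units of the grid
# the field lives on for displacement fields and in full-resolution voxel
# units for velocity fields. The compiled kernels use channel-first layout
# c(C, n1, n2, n3); the .int_* helpers convert.

.as_field_int <- function(f) {
  d <- dim(f)
  if (length(d) != 4L || d[4] != 3L)
    stop("vector field must be a 4-d array with dim (n1, n2, n3, 3)",
         call. = FALSE)
  aperm(f, c(4L, 1L, 2L, 3L))
}

.as_field_ext <- function(fi) aperm(fi, c(2L, 3L, 4L, 1L))

.vol_int <- function(v) {
  d <- dim(v)
  if (length(d) != 3L) stop("volume must be a 3-d array", call. = FALSE)
  array(as.double(v), dim = c(1L, d))
}

.vol_ext <- function(vi) array(vi, dim = dim(vi)[-1L])

.zero_field_int <- function(dims) array(0, dim = c(3L, dims))

.check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}

.grid_dims <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) d[-1L] else d
}

#' Pad a volume symmetrically to a dimension multiple
#'
#' Zero-pads a 3-d array symmetrically so every dimension becomes a multiple
#' of `multiple` (the sub-network encoders downsample by 16, so the
#' registration pipeline pads inputs to multiples of 16 and crops all outputs
#' back). Returns the padded array together with the index ranges of the
#' original data inside it.
#'
#' @param vol 3-d numeric array.
#' @param multiple positive integer the padded dimensions must divide by.
#' @return list with elements `data` (padded array) and `index` (list of 3
#'   integer vectors selecting the original region).
#' @export
pad_volume <- function(vol, multiple = 16L) {
  d <- dim(vol)
  target <- as.integer(ceiling(d / multiple) * multiple)
  if (all(target == d))
    return(list(data = vol, index = lapply(d, seq_len)))
  lo <- (target - d) %/% 2L
  out <- array(0, dim = target)
  idx <- lapply(1:3, function(a) seq.int(lo[a] + 1L, lo[a] + d[a]))
  out[idx[[1]], idx[[2]], idx[[3]]] <- vol
  list(data = out, index = idx)
}

.crop3 <- function(x, index) x[index[[1]], index[[2]], index[[3]], drop = FALSE]

.crop_field <- function(f, index) f[index[[1]], index[[2]], index[[3]], , drop = FALSE]

.normalize01 <- function(v) {
  rng <- range(v)
  if (rng[2] - rng[1] < .Machine$double.eps) return(array(0, dim = dim(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}
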