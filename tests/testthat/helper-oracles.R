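# Shared helpers: small independent oracles used across test files.

# Brute-force 3x3x3 stride-2 average pooling with replicate padding.
pool3_oracle <- function(vol) {
  n <- dim(vol)
  o <- (n - 1L) %/% 2L + 1L
  out <- array(0, dim = o)
  cl <- function(i, m) pmin(pmax(i, 1L), m)
  for (k in seq_len(o[3])) for (j in seq_len(o[2])) for (i in seq_len(o[1])) {
    vals <- c()
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1)
      vals <- c(vals, vol[cl(2L * i - 1L + di, n[1]),
                          cl(2L * j - 1L + dj, n[2]),
                          cl(2L * k - 1L + dk, n[3])])
    out[i, j, k] <- mean(vals)
  }
  out
}

# Per-voxel 3x3 finite-difference Jacobian determinant (plain R loops).
jacdet_oracle <- function(u) {
  n <- dim(u)[1:3]
  J <- array(0, dim = n)
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    M <- diag(3)
    idx <- c(i, j, k)
    for (ax in 1:3) {
      lo <- max(idx[ax] - 1L, 1L); hi <- min(idx[ax] + 1L, n[ax])
      p_hi <- idx; p_hi[ax] <- hi
      p_lo <- idx; p_lo[ax] <- lo
      for (comp in 1:3) {
        d <- (u[p_hi[1], p_hi[2], p_hi[3], comp] -
              u[p_lo[1], p_lo[2], p_lo[3], comp]) / (hi - lo)
        M[comp, ax] <- d + as.numeric(comp == ax)
      }
    }
    J[i, j, k] <- det(M)
  }
  J
}

# Mean |displacement| over an interior margin.
interior_mean_norm <- function(u, margin = 2L) {
  n <- dim(u)[1:3]
  idx <- lapply(n, function(m) seq.int(margin + 1L, m - margin))
  sub <- u[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  mean(sqrt(apply(sub^2, 1:3, sum)))
}

interior_max_norm <- function(u, margin = 2L) {
  n <- dim(u)[1:3]
  idx <- lapply(n, function(m) seq.int(margin + 1L, m - margin))
  sub <- u[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  max(sqrt(apply(sub^2, 1:3, sum)))
}
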