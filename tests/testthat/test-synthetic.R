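test_that("noise-free unblurred phantoms are piecewise constant", {
  ph <- make_phantom(c(24L, 24L, 24L), n_shells = 3L, noise_sd = 0,
                     blur_sigma = 0, seed = 1)
  expect_equal(length(unique(as.vector(ph$image))), 4L)  # background + shells
  expect_setequal(unique(as.vector(ph$labels)), 0:3)
  expect_error(make_phantom(c(8L, 24L, 24L)), "shape")
})

test_that("phantoms are bitwise reproducible under seed", {
  a <- make_phantom(c(24L, 24L, 24L), seed = 7)
  b <- make_phantom(c(24L, 24L, 24L), seed = 7)
  expect_identical(a, b)
  c_ <- make_phantom(c(24L, 24L, 24L), seed = 8)
  expect_false(identical(a$image, c_$image))
})

test_that("shell voxel counts match the analytic membership oracle", {
  ph <- make_phantom(c(24L, 28L, 24L), n_shells = 3L, seed = 3)
  geo <- ph$geometry
  n <- dim(ph$labels)
  count <- integer(3)
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    p <- t(geo$rotation) %*% (c(i, j, k) - 1 - geo$center)
    member <- 0L
    for (s in 1:3)
      if (sum((p / geo$semi_axes[[s]])^2) <= 1) member <- s
    if (member > 0L) count[member] <- count[member] + 1L
  }
  for (s in 1:3) expect_equal(sum(ph$labels == s), count[s])
})

test_that("random SVFs meet the amplitude contract and integrate fold-free", {
  v <- make_random_svf(c(24L, 24L, 24L), amplitude = 2,
                       smoothness_sigma = 4, seed = 5)
  nrm <- sqrt(apply(v^2, 1:3, sum))
  expect_equal(max(nrm), 2, tolerance = 1e-6)
  expect_gt(min(jacobian_determinant(integrate_svf(v))), 0)
  expect_identical(v, make_random_svf(c(24L, 24L, 24L), amplitude = 2,
                                      smoothness_sigma = 4, seed = 5))
  expect_error(make_random_svf(c(24L, 24L, 24L), amplitude = 0), "amplitude")
  # an absurd amplitude cannot be made diffeomorphic
  expect_error(make_random_svf(c(16L, 16L, 16L), amplitude = 60,
                               smoothness_sigma = 1, seed = 1),
               "fold-free")
})

test_that("smoothing shifts the field spectrum toward low frequencies", {
  set.seed(6)
  n <- 24L
  v <- make_random_svf(c(n, n, n), amplitude = 2, smoothness_sigma = 4,
                       seed = 9)
  white <- array(rnorm(n^3), dim = c(n, n, n))
  hf_energy <- function(a) {
    p <- abs(fft(a))^2
    freq <- pmin(0:(n - 1), n - (0:(n - 1)))  # symmetric frequency index
    hi <- outer(outer(freq > n / 4, freq > n / 4, "|"), freq > n / 4, "|")
    sum(p[hi]) / sum(p)
  }
  expect_lt(hf_energy(v[, , , 1] / max(abs(v))), hf_energy(white))
})

test_that("generated pairs respect their ground-truth warp", {
  pr0 <- make_pair(c(24L, 24L, 24L), amplitude = 0, seed = 2)
  expect_identical(pr0$fixed, pr0$moving)
  expect_identical(pr0$labels_fixed, pr0$labels_moving)
  expect_equal(dice_scores(pr0$labels_moving, pr0$labels_fixed)$mean, 1)

  pr <- make_pair(c(32L, 32L, 32L), amplitude = 3, smoothness_sigma = 5,
                  noise_sd = 0.02, seed = 4)
  d0 <- dice_scores(pr$labels_moving, pr$labels_fixed)$mean
  expect_lt(d0, 1)
  # round trip through the known inverse flow recovers the fixed image
  back <- warp_volume(pr$moving, integrate_svf(-pr$gt_svf))
  inner <- 4:29
  err <- mean(abs(back - pr$fixed)[inner, inner, inner])
  expect_lt(err, 0.02 + 0.05)   # noise floor + interpolation bound
})

test_that("pair generation at working scale stays fast", {
  t0 <- Sys.time()
  make_pair(c(64L, 64L, 64L), amplitude = 4, seed = 10)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
})
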