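test_that("pyramid halves dimensions and preserves constants", {
  vol <- array(3.7, dim = c(16, 24, 16))
  pyr <- build_pyramid(vol, 4L)
  expect_length(pyr, 4L)
  expect_identical(pyr[[4]], vol)
  expect_equal(dim(pyr[[3]]), c(8, 12, 8))
  expect_equal(dim(pyr[[2]]), c(4, 6, 4))
  expect_equal(dim(pyr[[1]]), c(2, 3, 2))
  for (p in pyr) expect_equal(range(p), c(3.7, 3.7))
  expect_error(build_pyramid(vol, 0L), "levels")
  vol[2, 2, 2] <- NA
  expect_error(build_pyramid(vol, 2L), "finite")
})

test_that("pyramid level shapes match the full-scale input geometry", {
  vol <- array(0, dim = c(176, 192, 176))
  pyr <- build_pyramid(vol, 4L)
  expect_equal(dim(pyr[[4]]), c(176, 192, 176))
  expect_equal(dim(pyr[[3]]), c(88, 96, 88))
  expect_equal(dim(pyr[[2]]), c(44, 48, 44))
  expect_equal(dim(pyr[[1]]), c(22, 24, 22))
})

test_that("one pooling step matches the brute-force window-mean oracle", {
  set.seed(1)
  vol <- array(0, dim = c(4, 4, 4))
  vol[2, 3, 2] <- 1
  expect_equal(build_pyramid(vol, 2L)[[1]], pool3_oracle(vol))
  vol2 <- array(rnorm(6 * 4 * 8), dim = c(6, 4, 8))
  expect_equal(build_pyramid(vol2, 2L)[[1]], pool3_oracle(vol2))
})

test_that("integrating a zero field gives the identity map", {
  v <- array(0, dim = c(8, 8, 8, 3))
  expect_equal(integrate_svf(v), v)
  expect_identical(formals(integrate_svf)$steps, 7L)
  expect_error(integrate_svf(v, steps = 0L), "steps")
})

test_that("scaling and squaring matches slow Euler integration", {
  v <- make_random_svf(c(24L, 24L, 24L), amplitude = 2, smoothness_sigma = 4,
                       seed = 5)
  u7 <- integrate_svf(v, 7L)
  ue <- svf_flow_euler(v, 1024L)
  expect_lt(interior_max_norm(u7 - ue, margin = 2L), 0.05)
  # step refinement: 10 steps moves the result by less than that bound
  u10 <- integrate_svf(v, 10L)
  expect_lt(interior_max_norm(u10 - u7, margin = 2L),
            interior_max_norm(u7 - ue, margin = 2L))
})

test_that("displacement composition identities and additivity hold", {
  set.seed(2)
  n <- c(10L, 10L, 10L)
  zero <- array(0, dim = c(n, 3L))
  f <- array(rnorm(prod(n) * 3, sd = 0.5), dim = c(n, 3L))
  expect_equal(compose_displacements(f, zero), f)
  expect_equal(compose_displacements(zero, f), f)
  t1 <- zero; t1[, , , 1] <- 2; t1[, , , 3] <- 1
  t2 <- zero; t2[, , , 1] <- -1; t2[, , , 2] <- 2
  comp <- compose_displacements(t2, t1)
  intr <- lapply(n, function(m) 3:(m - 3))
  expect_equal(comp[intr[[1]], intr[[2]], intr[[3]], ],
               (t1 + t2)[intr[[1]], intr[[2]], intr[[3]], ])
  expect_error(compose_displacements(f, array(0, dim = c(8, 8, 8, 3))),
               "grid")
})

test_that("warping identities: zero field, integer shift, nearest labels", {
  set.seed(3)
  n <- c(9L, 9L, 9L)
  vol <- array(rnorm(prod(n)), dim = n)
  zero <- array(0, dim = c(n, 3L))
  expect_equal(warp_volume(vol, zero), vol)
  sh <- zero; sh[, , , 1] <- 2
  w <- warp_volume(vol, sh)
  expect_equal(w[1:7, , ], vol[3:9, , ])
  labs <- array(sample(0:3, prod(n), TRUE), dim = n)
  f <- array(rnorm(prod(n) * 3, sd = 1.5), dim = c(n, 3L))
  wl <- warp_volume(labs, f, "nearest")
  expect_true(all(wl %in% 0:3))
  expect_error(warp_volume(vol, zero, "bicubic"))
})

test_that("field upsampling interpolates linearly and reproduces nodes", {
  cf <- array(2.5, dim = c(4, 4, 4, 3))
  up <- upsample_field(cf, c(7L, 7L, 7L))
  expect_equal(range(up), c(2.5, 2.5))
  expect_equal(dim(up), c(7L, 7L, 7L, 3L))
  ramp <- array(0, dim = c(2, 2, 2, 3))
  ramp[2, , , 1] <- 4
  up3 <- upsample_field(ramp, c(3L, 3L, 3L))
  expect_equal(up3[2, 1, 1, 1], 2)   # midpoint = arithmetic mean
  expect_equal(up3[c(1, 3), 1, 1, 1], c(0, 4))
  set.seed(4)
  src <- array(rnorm(5^3 * 3), dim = c(5, 5, 5, 3))
  fine <- upsample_field(src, c(9L, 9L, 9L))  # 2x axis-aligned refinement
  expect_equal(fine[seq(1, 9, 2), seq(1, 9, 2), seq(1, 9, 2), ], src)
  expect_error(upsample_field(src, c(3L, 3L, 3L)), "target_shape")
})

test_that("Gaussian smoothing layer normalizes, preserves constants", {
  cf <- array(-1.2, dim = c(6, 6, 6, 3))
  expect_equal(gaussian_smooth_field(cf), cf)
  expect_error(gaussian_smooth_field(cf, ksize = 4L), "odd")
  # impulse response in the interior equals the separable kernel product
  imp <- array(0, dim = c(7, 7, 7, 3))
  imp[4, 4, 4, 2] <- 1
  sm <- gaussian_smooth_field(imp, sigma = 1.732, ksize = 3L)
  k1 <- exp(-(c(-1, 0, 1))^2 / (2 * 1.732^2))
  k1 <- k1 / sum(k1)
  expect_equal(sm[3:5, 3:5, 3:5, 2],
               outer(outer(k1, k1), k1), tolerance = 1e-12)
  expect_equal(sum(sm[, , , 1]), 0)
})

test_that("Jacobian determinant matches linear maps and a direct oracle", {
  n <- c(8L, 8L, 8L)
  zero <- array(0, dim = c(n, 3L))
  expect_equal(jacobian_determinant(zero), array(1, dim = n))
  # global scaling x -> s x gives J = s^3
  s <- 1.2
  g <- array(0, dim = c(n, 3L))
  for (a in 1:3) {
    coord <- slice.index(zero[, , , 1], a) - 1
    g[, , , a] <- (s - 1) * coord
  }
  J <- jacobian_determinant(g)
  expect_equal(J[3:6, 3:6, 3:6], array(s^3, dim = c(4, 4, 4)),
               tolerance = 1e-12)
  set.seed(5)
  u <- array(rnorm(prod(n) * 3, sd = 0.3), dim = c(n, 3L))
  expect_equal(jacobian_determinant(u), jacdet_oracle(u), tolerance = 1e-12)
})

test_that("random smooth SVFs integrate to fold-free, invertible maps", {
  for (seed in 1:4) {
    v <- make_random_svf(c(24L, 24L, 24L), amplitude = 2,
                         smoothness_sigma = 4, seed = seed)
    u_fwd <- integrate_svf(v)
    u_inv <- integrate_svf(-v)
    expect_gt(min(jacobian_determinant(u_fwd)), 0)
    round_trip <- compose_displacements(u_inv, u_fwd)
    expect_lt(interior_mean_norm(round_trip, margin = 2L), 0.1)
  }
})

test_that("padding restores the original region and pads to the multiple", {
  vol <- array(rnorm(20 * 24 * 18), dim = c(20, 24, 18))
  p <- pad_volume(vol, 16L)
  expect_equal(dim(p$data), c(32, 32, 32))
  expect_equal(p$data[p$index[[1]], p$index[[2]], p$index[[3]]], vol)
  q <- pad_volume(array(0, dim = c(32, 32, 32)), 16L)
  expect_equal(dim(q$data), c(32, 32, 32))
})
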