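test_that("NCC identities: self-correlation and affine invariance", {
  set.seed(10)
  img <- array(rnorm(10^3), dim = c(10, 10, 10))
  expect_equal(ncc(img, img, "global"), 1, tolerance = 1e-4)
  expect_equal(ncc(img, img, 9L), 1, tolerance = 1e-4)
  expect_equal(ncc(img, 2.5 * img + 3, "global"), 1, tolerance = 1e-4)
  expect_equal(ncc(img, -1.5 * img + 0.2, "global"), -1, tolerance = 1e-4)
  cst <- array(2, dim = c(10, 10, 10))
  expect_equal(ncc(cst, cst, "global"), 0)
  expect_error(ncc(img, img[1:5, , ], "global"), "shape")
  expect_error(ncc(img, img, 4L), "odd")
})

test_that("global NCC matches a direct two-pass Pearson oracle", {
  set.seed(11)
  a <- array(rnorm(8^3), dim = c(8, 8, 8))
  b <- array(rnorm(8^3), dim = c(8, 8, 8))
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  cv <- sum((a - ma) * (b - mb)) / n
  va <- sum((a - ma)^2) / n; vb <- sum((b - mb)^2) / n
  oracle <- cv / sqrt(va * vb + 1e-5)
  expect_equal(ncc(a, b, "global"), oracle, tolerance = 1e-6)
})

test_that("windowed NCC averages window-cropped local correlations", {
  set.seed(12)
  a <- array(rnorm(6^3), dim = c(6, 6, 6))
  b <- array(rnorm(6^3), dim = c(6, 6, 6))
  w <- 3L; r <- 1L
  vals <- array(0, dim = dim(a))
  for (k in 1:6) for (j in 1:6) for (i in 1:6) {
    ii <- max(1, i - r):min(6, i + r)
    jj <- max(1, j - r):min(6, j + r)
    kk <- max(1, k - r):min(6, k + r)
    aa <- a[ii, jj, kk]; bb <- b[ii, jj, kk]
    cc <- sum((aa - mean(aa)) * (bb - mean(bb)))
    va <- sum((aa - mean(aa))^2); vb <- sum((bb - mean(bb))^2)
    vals[i, j, k] <- cc / sqrt(va * vb + 1e-5)
  }
  expect_equal(ncc(a, b, w), mean(vals), tolerance = 1e-10)
})

test_that("TV regularizer: zero on constants, homogeneous, shift-invariant", {
  cf <- array(4.2, dim = c(8, 8, 8, 3))
  expect_equal(tv_regularizer(cf), 0)
  set.seed(13)
  v <- array(rnorm(8^3 * 3), dim = c(8, 8, 8, 3))
  expect_equal(tv_regularizer(3 * v), 3 * tv_regularizer(v))
  expect_equal(tv_regularizer(-2 * v), 2 * tv_regularizer(v))
  expect_equal(tv_regularizer(v + 7), tv_regularizer(v))
})

test_that("TV of a unit ramp matches the explicit summation oracle", {
  n <- c(8L, 8L, 8L)
  v <- array(0, dim = c(n, 3L))
  v[, , , 1] <- slice.index(v[, , , 1], 1) - 1   # v_x = x
  # direct loop: forward differences of each channel along each axis
  total <- 0
  for (comp in 1:3) for (ax in 1:3) {
    d <- apply(v[, , , comp], setdiff(1:3, ax), diff)
    total <- total + sum(abs(d))
  }
  expect_equal(tv_regularizer(v), total / prod(n))
  # ramp: 7*64 unit differences per the x-axis of channel 1 only
  expect_equal(tv_regularizer(v), 7 * 64 / 512)
})

test_that("identity registration of identical volumes scores -2 per term", {
  set.seed(14)
  # large-scale structure so every pyramid level keeps variance well above
  # the epsilon guard of the correlation
  ramp <- slice.index(array(0, dim = c(16, 16, 16)), 1) +
    2 * slice.index(array(0, dim = c(16, 16, 16)), 2)
  vol <- ramp + array(runif(16^3), dim = c(16, 16, 16))
  pyr <- build_pyramid(vol, 4L)
  svfs <- lapply(1:3, function(l) array(0, dim = c(dim(pyr[[l]]), 3L)))
  cfg <- mdreg_config(levels = 3L, full_res_sim = FALSE)
  lb <- multires_loss(pyr, pyr, svfs, cfg)
  expect_equal(lb$per_level_similarity_fwd, rep(1, 3), tolerance = 1e-3)
  expect_equal(lb$per_level_similarity_inv, rep(1, 3), tolerance = 1e-3)
  expect_equal(lb$per_level_tv, rep(0, 3))
  expect_equal(lb$total, -2 * 3, tolerance = 5e-3)
  cfg$full_res_sim <- TRUE
  lb4 <- multires_loss(pyr, pyr, svfs, cfg)
  expect_length(lb4$per_level_similarity_fwd, 4L)
  expect_equal(lb4$total, -2 * 4, tolerance = 5e-3)
})

test_that("breakdown total follows the lambda-weighted formula exactly", {
  set.seed(15)
  fix <- array(runif(16^3), dim = c(16, 16, 16))
  mov <- array(runif(16^3), dim = c(16, 16, 16))
  pf <- build_pyramid(fix, 4L); pm <- build_pyramid(mov, 4L)
  svfs <- lapply(1:3, function(l)
    array(rnorm(prod(dim(pf[[l]])) * 3, sd = 0.5),
          dim = c(dim(pf[[l]]), 3L)))
  for (lam in c(0, 0.35)) {
    cfg <- mdreg_config(levels = 3L, lambda = lam)
    lb <- multires_loss(pf, pm, svfs, cfg)
    expect_equal(lb$total,
                 sum(-lb$per_level_similarity_fwd -
                     lb$per_level_similarity_inv + lam * lb$per_level_tv))
  }
  expect_error(multires_loss(pf, pm, svfs[1:2], mdreg_config(levels = 3L)),
               "levels")
})

test_that("single-level loss matches a hand-assembled oracle", {
  set.seed(16)
  n <- c(16L, 16L, 16L)
  fix <- array(runif(prod(n)), dim = n)
  mov <- array(runif(prod(n)), dim = n)
  pf <- build_pyramid(fix, 2L); pm <- build_pyramid(mov, 2L)
  v1 <- array(rnorm(8^3 * 3, sd = 1), dim = c(8, 8, 8, 3))
  cfg <- mdreg_config(levels = 1L, lambda = 0.35, ncc_window = 9L)
  lb <- multires_loss(pf, pm, list(v1), cfg)
  # oracle: chain the public primitives by hand
  fac <- (8 - 1) / (16 - 1)          # full-res voxel units -> level units
  up <- integrate_svf(v1 * fac, 7L)
  um <- integrate_svf(-v1 * fac, 7L)
  s_f <- ncc(pf[[1]], warp_volume(pm[[1]], up), 9L)
  s_i <- ncc(pm[[1]], warp_volume(pf[[1]], um), 9L)
  vfull <- upsample_field(v1, n)
  uf <- gaussian_smooth_field(integrate_svf(vfull, 7L))
  ui <- gaussian_smooth_field(integrate_svf(-vfull, 7L))
  s_ff <- ncc(fix, warp_volume(mov, uf), 9L)
  s_fi <- ncc(mov, warp_volume(fix, ui), 9L)
  # TV acts on the increment in its own grid's voxel units
  oracle_total <- -(s_f + s_i + s_ff + s_fi) + 0.35 * tv_regularizer(v1 * fac)
  expect_equal(lb$per_level_similarity_fwd, c(s_f, s_ff), tolerance = 1e-10)
  expect_equal(lb$per_level_similarity_inv, c(s_i, s_fi), tolerance = 1e-10)
  expect_equal(lb$total, oracle_total, tolerance = 1e-10)
})
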