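test_that("sub-network output grids sit at 1/8, 1/4 and 1/2 resolution", {
  set.seed(20)
  n <- c(32L, 32L, 32L)
  x <- array(rnorm(2 * prod(n)), dim = c(2L, n))
  for (level in 1:3) {
    net <- build_subnetwork(level)
    out <- mdreg:::.subnet_forward(net, x)$out
    expect_equal(dim(out), c(3L, n / 2^(4 - level)))
    # zero-initialized output layer emits the identity transform
    expect_equal(max(abs(out)), 0)
  }
  expect_error(build_subnetwork(4), "level")
  expect_error(build_subnetwork(0), "level")
})

test_that("anisotropic input grids downsample consistently", {
  set.seed(21)
  x <- array(rnorm(2 * 64 * 32 * 16), dim = c(2L, 64L, 32L, 16L))
  net <- build_subnetwork(1)
  expect_equal(dim(mdreg:::.subnet_forward(net, x)$out), c(3L, 8L, 4L, 2L))
})

test_that("repeated builds under one seed are identical, forward deterministic", {
  make <- function() {
    set.seed(99)
    build_subnetwork(2)
  }
  n1 <- make(); n2 <- make()
  expect_identical(n1, n2)
  x <- array(rnorm(2 * 32^3), dim = c(2L, 32L, 32L, 32L))
  expect_identical(mdreg:::.subnet_forward(n1, x)$out,
                   mdreg:::.subnet_forward(n2, x)$out)
})

test_that("accumulated field at the coarsest level equals its increment", {
  set.seed(22)
  ph <- make_phantom(c(32L, 32L, 32L), seed = 1)
  nets <- lapply(1:3, build_subnetwork)
  # give the networks nonzero output so the accumulation is exercised
  for (l in 1:3) {
    last <- length(nets[[l]]$layers)
    nets[[l]]$layers[[last]]$W[] <- rnorm(length(nets[[l]]$layers[[last]]$W),
                                          sd = 0.01)
    nets[[l]]$layers[[last]]$b <- rnorm(3, sd = 0.1)
  }
  st <- forward_multires(ph$image, warp_volume(ph$image,
                                               array(0, c(32, 32, 32, 3))),
                         nets, mdreg_config())
  expect_equal(st$accumulated[[1]], st$svfs[[1]])
  expect_equal(dim(st$svfs[[1]]), c(4L, 4L, 4L, 3L))
  expect_equal(dim(st$svfs[[3]]), c(16L, 16L, 16L, 3L))
})

test_that("zero networks leave the moving image untouched", {
  ph <- make_phantom(c(32L, 32L, 32L), seed = 2)
  nets <- lapply(1:3, build_subnetwork)
  st <- forward_multires(ph$image, ph$image, nets, mdreg_config())
  expect_equal(max(abs(st$forward_field)), 0)
  expect_equal(st$warped_moving, ph$image)
  for (v in st$svfs) expect_equal(max(abs(v)), 0)
})

test_that("a hand-set constant coarse velocity reproduces the manual chain", {
  ph <- make_phantom(c(32L, 32L, 32L), seed = 3)
  nets <- lapply(1:3, build_subnetwork)
  cst <- c(1.5, -0.8, 0.6)
  last <- length(nets[[1]]$layers)
  nets[[1]]$layers[[last]]$b <- cst   # constant v1, weights stay zero
  cfg <- mdreg_config()
  st <- forward_multires(ph$image, ph$image, nets, cfg)
  for (c_ in 1:3)
    expect_equal(range(st$svfs[[1]][, , , c_]), rep(cst[c_], 2))
  # manual pipeline: upsample -> integrate -> smooth
  v1 <- st$svfs[[1]]
  manual <- gaussian_smooth_field(
    integrate_svf(upsample_field(v1, c(32L, 32L, 32L)), cfg$steps),
    cfg$sigma, cfg$ksize)
  expect_equal(st$forward_field, manual, tolerance = 1e-12)
})

test_that("one loss backward pass reaches every sub-network", {
  set.seed(23)
  pr <- make_pair(c(32L, 32L, 32L), amplitude = 3, seed = 4)
  cfg <- mdreg_config()
  pp <- mdreg:::.prep_pair(pr$fixed, pr$moving)
  pyr <- mdreg:::.pair_pyramids(pp$fix, pp$mov, cfg$levels)
  nets <- lapply(1:3, build_subnetwork)
  stp <- mdreg:::.loss_step(nets, pp$fix, pp$mov, pyr$pf, pyr$pm, cfg)
  for (l in 1:3) {
    gsum <- sum(vapply(stp$grads[[l]],
                       function(g) sum(abs(g$gw)) + sum(abs(g$gb)), 0))
    expect_gt(gsum, 0)
  }
})
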