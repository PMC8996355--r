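test_that("Dice identities: perfect overlap, disjoint masks, worked example", {
  n <- c(10L, 10L, 10L)
  a <- array(0L, dim = n)
  a[2:4, 2:4, 2:4] <- 1L
  expect_equal(dice_scores(a, a)$mean, 1)
  b <- array(0L, dim = n)
  b[7:9, 7:9, 7:9] <- 1L
  expect_equal(dice_scores(a, b)$mean, 0)
  # 2x2x2 cube against itself shifted by one voxel: dice = 2*4/(8+8)
  A <- array(0L, dim = n); A[3:4, 3:4, 3:4] <- 1L
  B <- array(0L, dim = n); B[4:5, 3:4, 3:4] <- 1L
  expect_equal(dice_scores(A, B)$per_label[["1"]], 0.5)
  expect_error(dice_scores(A, B, labels = integer(0)), "empty")
})

test_that("Dice is symmetric, permutation-invariant, unweighted in the mean", {
  set.seed(30)
  n <- c(12L, 12L, 12L)
  a <- array(sample(0:3, prod(n), TRUE), dim = n)
  b <- array(sample(0:3, prod(n), TRUE), dim = n)
  da <- dice_scores(a, b); db <- dice_scores(b, a)
  expect_equal(da$per_label, db$per_label)
  expect_equal(da$mean, mean(da$per_label))
  # permute label identities consistently in both maps
  perm <- c(0L, 3L, 1L, 2L)
  ap <- array(perm[a + 1L], dim = n); bp <- array(perm[b + 1L], dim = n)
  dp <- dice_scores(ap, bp)
  expect_equal(sort(unname(dp$per_label)), sort(unname(da$per_label)))
})

test_that("folding statistics count non-positive Jacobians in the mask", {
  n <- c(12L, 12L, 12L)
  zero <- array(0, dim = c(n, 3L))
  mask <- array(1, dim = n)
  fs <- folding_stats(zero, mask)
  expect_equal(fs$count, 0L)
  expect_equal(fs$percent, 0)
  expect_error(folding_stats(zero, array(0, dim = n)), "empty mask")

  # 1-D fold: u_x = -2x flips orientation, J = -1 on the strip
  u <- array(0, dim = c(n, 3L))
  coord <- slice.index(u[, , , 1], 1) - 1
  u[, , , 1] <- -2 * coord
  J <- jacobian_determinant(u)
  strip <- array(FALSE, dim = n); strip[4:9, 4:9, 4:9] <- TRUE
  expect_equal(unique(as.vector(J[strip])), -1)
  # direct loop oracle over the strip
  oracle <- sum(J[strip] <= 0)
  fs2 <- folding_stats(u, strip)
  expect_equal(fs2$count, as.integer(oracle))
  expect_equal(fs2$count, sum(strip))

  # restricting the mask restricts the count to that region
  half <- array(FALSE, dim = n); half[1:6, , ] <- TRUE
  full <- folding_stats(u, array(TRUE, dim = n))
  expect_equal(folding_stats(u, half)$count,
               sum(jacobian_determinant(u)[half] <= 0))
  expect_lte(folding_stats(u, half)$count, full$count)
})

test_that("direction-wise evaluation of an identity fit is perfect", {
  pr <- make_pair(c(32L, 32L, 32L), amplitude = 0, seed = 5)
  fit <- mdreg(pr$fixed, pr$moving,
               cfg = mdreg_config(iterations = 0L), mode = "instance")
  for (dd in c("forward", "inverse")) {
    ev <- evaluate_direction(fit, pr$labels_fixed, pr$labels_moving, dd)
    expect_equal(ev$mean_dice, 1)
    expect_equal(ev$folding_count, 0L)
    expect_equal(ev$folding_percent, 0)
    expect_equal(ev$direction, dd)
  }
})

test_that("the fixture's ground-truth warp evaluates to dice 1 against itself", {
  pr <- make_pair(c(32L, 32L, 32L), amplitude = 3, seed = 6)
  warped <- warp_volume(pr$labels_fixed, pr$gt_disp, "nearest")
  expect_equal(dice_scores(warped, pr$labels_moving)$mean, 1)
})
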