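test_that("pair sampling covers all ordered pairs uniformly", {
  expect_error(sample_pairs(character(0), 10), "empty")
  p1 <- sample_pairs("a", 25, seed = 1)
  expect_true(all(p1$fixed == "a" & p1$moving == "a"))
  expect_identical(sample_pairs(letters[1:5], 100, seed = 42),
                   sample_pairs(letters[1:5], 100, seed = 42))
  # n = 3: the 9 ordered pairs should be uniform within 3 sigma at 9000 draws
  p <- sample_pairs(1:3, 9000, seed = 7)
  counts <- table(paste(p$fixed, p$moving))
  expect_length(counts, 9L)
  expected <- 9000 / 9
  sigma <- sqrt(9000 * (1 / 9) * (8 / 9))
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("instance mode with zero iterations is the identity transform", {
  pr <- make_pair(c(32L, 32L, 32L), amplitude = 2, seed = 8)
  fit <- mdreg(pr$fixed, pr$moving, cfg = mdreg_config(iterations = 0L))
  expect_equal(max(abs(fit$forward_field)), 0)
  expect_equal(fit$warped_moving, mdreg:::.normalize01(pr$moving))
})

test_that("warped moving is exactly the moving image under the forward field", {
  pr <- make_pair(c(32L, 32L, 32L), amplitude = 2, seed = 9)
  fit <- mdreg(pr$fixed, pr$moving,
               cfg = mdreg_config(iterations = 5L, learning_rate = 1e-3))
  expect_identical(fit$warped_moving,
                   warp_volume(fit$moving, fit$forward_field))
  expect_identical(fit$warped_fixed,
                   warp_volume(fit$fixed, fit$inverse_field))
})

test_that("short self-registration keeps the identity and reduces the loss", {
  ph <- make_phantom(c(32L, 32L, 32L), seed = 10)
  cfg <- mdreg_config(iterations = 30L, learning_rate = 1e-3, seed = 2L)
  fit <- mdreg(ph$image, ph$image, cfg = cfg)
  expect_lte(fit$loss_trace$total[30L], fit$loss_trace$total[1L])
  mags <- sqrt(apply(fit$forward_field^2, 1:3, sum))
  expect_lt(mean(mags), 0.5)
})

test_that("configuration defaults mirror the training protocol", {
  cfg <- mdreg_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 1L)
  expect_equal(cfg$iterations, 150000L)
  expect_equal(cfg$lambda, 0.35)
  expect_equal(cfg$sigma, 1.732)
  expect_equal(cfg$ksize, 3L)
  expect_equal(cfg$steps, 7L)
  expect_error(mdreg_config(lambda = -1), "lambda")
  expect_error(mdreg_config(ncc_window = 8), "odd")
})

test_that("population training is deterministic and logs every iteration", {
  vols <- list(make_phantom(c(32L, 32L, 32L), seed = 1)$image,
               make_phantom(c(32L, 32L, 32L), seed = 2)$image)
  cfg <- mdreg_config(iterations = 4L, learning_rate = 1e-4, seed = 5L)
  m1 <- mdreg_train(vols, cfg)
  m2 <- mdreg_train(vols, cfg)
  expect_equal(nrow(m1$loss_trace), 4L)
  expect_identical(m1$loss_trace, m2$loss_trace)   # bitwise determinism
  expect_identical(m1$nets, m2$nets)
  # feedforward application of the trained model runs end to end
  fit <- mdreg(vols[[1]], vols[[2]], cfg = cfg, mode = "feedforward",
               model = m1)
  expect_equal(dim(fit$forward_field), c(32L, 32L, 32L, 3L))
  expect_error(mdreg(vols[[1]], vols[[2]], mode = "feedforward"),
               "mdreg_model")
})

test_that("register_pair dispatches on weights or instance mode", {
  pr <- make_pair(c(32L, 32L, 32L), amplitude = 0, seed = 3)
  fit <- register_pair(pr$fixed, pr$moving, "instance",
                       cfg = mdreg_config(iterations = 0L))
  expect_s3_class(fit, "mdreg")
  expect_error(register_pair(pr$fixed, pr$moving, "nonsense"),
               "instance")
})

test_that("model methods expose the fit: summary, predict, residuals", {
  pr <- make_pair(c(32L, 32L, 32L), amplitude = 2, seed = 12)
  fit <- mdreg(pr$fixed, pr$moving,
               cfg = mdreg_config(iterations = 5L, learning_rate = 1e-3))
  s <- summary(fit)
  expect_s3_class(s, "summary.mdreg")
  expect_true(is.finite(s$ncc_after))
  wl <- predict(fit, pr$labels_moving, what = "labels")
  expect_true(all(wl %in% 0:3))
  wi <- predict(fit, direction = "inverse")
  expect_equal(dim(wi), dim(pr$fixed))
  expect_equal(residuals(fit), fit$fixed - fit$warped_moving)
  expect_output(print(fit), "instance mode")
  expect_output(print(s), "Jacobian")
})
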