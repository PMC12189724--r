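test_that("normalization centres and scales each channel separately", {
  set.seed(31)
  arrays <- lapply(1:5, function(i) {
    a <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    a[, , 2] <- a[, , 2] * 4 + 10
    a
  })
  st <- channel_stats(arrays)
  normed <- lapply(arrays, normalize_channels, stats = st)
  pooled <- do.call(rbind, lapply(normed, function(a) matrix(a, ncol = 3)))
  expect_lt(max(abs(colMeans(pooled))), 1e-6)
  expect_lt(max(abs(apply(pooled, 2, sd) - 1)), 1e-2)
  # exact inverse
  x <- arrays[[1]]
  expect_equal(normalize_channels(normalize_channels(x, st), st,
                                  invert = TRUE), x, tolerance = 1e-10)
  # statistics from one split leave another split off-centre
  other <- array(rnorm(8 * 8 * 3, mean = 2), c(8, 8, 3))
  expect_gt(abs(mean(normalize_channels(other, st)[, , 1])), 0.5)
  # degenerate channel is refused
  flat <- list(array(1, c(4, 4, 2)))
  expect_error(normalize_channels(flat[[1]], channel_stats(flat)),
               "degenerate")
})

test_that("gaussian blur preserves constants, mass, and reduces variance", {
  const <- array(2, c(12, 12, 3))
  expect_equal(gaussian_blur(const), const, tolerance = 1e-10)
  # impulse response: discretized Gaussian summing to one
  imp <- matrix(0, 15, 15)
  imp[8, 8] <- 1
  resp <- gaussian_blur(imp, 5, 1)
  expect_equal(sum(resp), 1, tolerance = 1e-12)
  expect_equal(resp[8, 8], max(resp))
  k <- dnorm(-2:2)
  k <- k / sum(k)
  expect_equal(resp[6:10, 6:10], outer(k, k), tolerance = 1e-12)
  # smoothing reduces the variance of white noise
  set.seed(32)
  noise <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  expect_lt(var(as.numeric(gaussian_blur(noise))), var(as.numeric(noise)))
  expect_error(gaussian_blur(noise, sigma = 0), "positive")
  expect_error(gaussian_blur(noise, kernel = 4), "odd")
  # adjoint identity for the backprop operator
  a <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  b <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  adj <- asNamespace("spectrastain")$gaussian_blur_adjoint
  expect_equal(sum(gaussian_blur(a) * b), sum(a * adj(b)),
               tolerance = 1e-10)
})

test_that("total variation matches hand summation and is homogeneous", {
  img <- array(0, c(2, 2, 3))
  img[, , 1] <- c(0, 0, 1, 1)   # column-major: [[0,1],[0,1]]
  expect_equal(total_variation(img), 2)
  expect_equal(total_variation(array(5, c(7, 7, 3))), 0)
  set.seed(33)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  expect_equal(total_variation(2.5 * x), 2.5^2 * total_variation(x))
  # brute-force oracle on a random small image
  ref <- 0
  for (c in 1:3) {
    for (i in 1:5) for (j in 1:6) ref <- ref + (x[i, j, c] - x[i + 1, j, c])^2
    for (i in 1:6) for (j in 1:5) ref <- ref + (x[i, j, c] - x[i, j + 1, c])^2
  }
  expect_equal(total_variation(x), ref, tolerance = 1e-12)
  # gradient check
  tvg <- asNamespace("spectrastain")$tv_grad(x)
  eps <- 1e-6
  i <- 17
  xp <- x
  xp[i] <- x[i] + eps
  xm <- x
  xm[i] <- x[i] - eps
  expect_equal(tvg[i],
               (total_variation(xp) - total_variation(xm)) / (2 * eps),
               tolerance = 1e-6)
})

test_that("generator loss assembles its three terms", {
  cfg <- loss_config()
  const_g <- array(0.5, c(8, 8, 3))
  # perfect generation with a fooled discriminator: loss tends to zero
  l <- generator_loss(1 - 1e-12, const_g, const_g, cfg)
  expect_lt(l$total, 1e-9)
  # gamma1 = gamma2 = 0 leaves the pure adversarial term
  set.seed(34)
  a <- array(runif(8 * 8 * 3), c(8, 8, 3))
  b <- array(runif(8 * 8 * 3), c(8, 8, 3))
  l0 <- generator_loss(0.3, a, b, loss_config(gamma1 = 0, gamma2 = 0))
  expect_equal(l0$total, -log(0.3))
  # term-by-term oracle
  lf <- generator_loss(0.5, a, b, cfg)
  expect_equal(lf$adversarial, -log(0.5))
  expect_equal(lf$l1, mean(abs(gaussian_blur(a) - gaussian_blur(b))))
  expect_equal(lf$tv, total_variation(a))
  expect_equal(lf$total,
               -log(0.5) + 500 * lf$l1 + 1e-4 * lf$tv, tolerance = 1e-12)
  expect_error(generator_loss(1.2, a, b, cfg), "0, 1")
  expect_error(loss_config(blur_kernel = 4), "odd")
})

test_that("discriminator loss has the textbook fixed points", {
  expect_equal(discriminator_loss(0.5, 0.5), log(2))
  expect_lt(discriminator_loss(1 - 1e-12, 1e-12), 1e-9)
  # minimized at d_real -> 1 and d_fake -> 0
  expect_gt(discriminator_loss(0.7, 0.5), discriminator_loss(0.9, 0.5))
  expect_gt(discriminator_loss(0.9, 0.5), discriminator_loss(0.9, 0.1))
  expect_error(discriminator_loss(0, 0.5), "0, 1")
  # patch grids are averaged
  expect_equal(discriminator_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
               log(2))
})

test_that("the learning-rate staircase follows the published schedule", {
  tc <- train_config()
  expect_equal(lr_at_epoch(tc, 1), 0.02)
  expect_equal(lr_at_epoch(tc, 4), 0.02)
  expect_equal(lr_at_epoch(tc, 10), 0.02 * 0.85^2)  # 0.01445
  expect_equal(lr_at_epoch(tc, 100), 0.02 * 0.85^20)
  expect_equal(lr_at_epoch(train_config(lr = 0.1, lr_decay = 0.5,
                                        decay_every = 2), 6), 0.1 * 0.5^3)
})

test_that("a short training run learns and is reproducible", {
  ds <- build_dataset(n_pairs = 6, image_size = 64, patch = 32,
                      stride = 32, n_groups = 3, test_groups = 3, seed = 5)
  dsp <- prepare_inputs(ds, "pca", 3)
  cfg <- generator_config(3, depth = 2, base_width = 8)
  tc <- train_config(epochs = 3, seed = 9)
  ck <- vs_train(dsp, gen_cfg = cfg, train_cfg = tc)
  expect_s3_class(ck, "vs_checkpoint")
  expect_equal(nrow(ck$history), 3)
  # learning happened
  expect_lt(ck$history$loss_g_l1[3], ck$history$loss_g_l1[1])
  # identical seeds give identical histories
  ck2 <- vs_train(dsp, gen_cfg = cfg, train_cfg = tc)
  expect_equal(ck$history, ck2$history, tolerance = 1e-10)
  # staining: shape, range, determinism
  out <- vs_stain(ck, dsp$test[[1]]$input)
  expect_equal(dim(out), c(32, 32, 3))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, vs_stain(ck, dsp$test[[1]]$input))
  expect_error(vs_stain(ck, array(0, c(32, 32, 7))), "channels")
  # checkpoint round trip through disk
  path <- tempfile(fileext = ".rds")
  write_checkpoint(ck, path)
  ck3 <- read_checkpoint(path)
  expect_identical(vs_stain(ck3, dsp$test[[1]]$input), out)
})
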