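test_that("spatial metrics match hand arithmetic and brute force", {
  a0 <- array(0, c(2, 2, 3))
  a1 <- array(1, c(2, 2, 3))
  expect_equal(metric_l1(a0, a0), 0)
  expect_equal(metric_rmse(a0, a0), 0)
  expect_equal(metric_l1(a0, a1), 1)
  expect_equal(metric_rmse(a0, a1), 1)
  # 2x1 images (0,1) vs (1,1)
  x <- matrix(c(0, 1), 2, 1)
  y <- matrix(c(1, 1), 2, 1)
  expect_equal(metric_l1(x, y), 0.5)
  expect_equal(metric_rmse(x, y), 1 / sqrt(2))
  # brute-force loop on a random 4x4 pair
  set.seed(41)
  p <- array(runif(4 * 4 * 3), c(4, 4, 3))
  q <- array(runif(4 * 4 * 3), c(4, 4, 3))
  acc_l1 <- 0
  acc_sq <- 0
  for (i in 1:4) for (j in 1:4) for (c in 1:3) {
    acc_l1 <- acc_l1 + abs(p[i, j, c] - q[i, j, c])
    acc_sq <- acc_sq + (p[i, j, c] - q[i, j, c])^2
  }
  expect_equal(metric_l1(p, q), acc_l1 / 48, tolerance = 1e-12)
  expect_equal(metric_rmse(p, q), sqrt(acc_sq / 48), tolerance = 1e-12)
  expect_error(metric_l1(p, q[1:3, , ]), "identical")
})

test_that("PSNR follows its logarithmic law", {
  a <- matrix(0, 10, 10)
  b <- a
  b[] <- sqrt(0.01)              # MSE = 0.01 exactly
  expect_equal(metric_psnr(a, b), 20)
  expect_equal(metric_psnr(a, a), Inf)
  # doubling the MSE costs ~3.01 dB
  b2 <- a
  b2[] <- sqrt(0.02)
  expect_equal(metric_psnr(a, b) - metric_psnr(a, b2), 10 * log10(2))
})

test_that("SSIM satisfies identity, symmetry and contrast inversion", {
  set.seed(42)
  a <- array(runif(24 * 24 * 3), c(24, 24, 3))
  expect_equal(metric_ssim(a, a), 1, tolerance = 1e-9)
  b <- array(runif(24 * 24 * 3), c(24, 24, 3))
  expect_equal(metric_ssim(a, b), metric_ssim(b, a), tolerance = 1e-12)
  # structural inversion of a high-contrast pattern scores poorly
  pat <- matrix(rep(c(0, 1), length.out = 24 * 24), 24, 24)
  pat <- gaussian_blur(pat, 5, 1)
  expect_lt(metric_ssim(pat, 1 - pat), 0.5)
  expect_error(metric_ssim(a[1:8, 1:8, ], a[1:8, 1:8, ]), "window")
})

test_that("FID has closed-form behaviour on Gaussian features", {
  set.seed(43)
  f <- matrix(rnorm(300 * 8), 300, 8)
  # identity of indiscernibles
  expect_lt(metric_fid(f, f), 1e-6)
  # symmetry
  g <- matrix(rnorm(300 * 8), 300, 8) + 1
  expect_equal(metric_fid(f, g), metric_fid(g, f), tolerance = 1e-8)
  expect_gte(metric_fid(f, g), 0)
  # shifted identity-covariance Gaussians: FID ~ ||delta mu||^2
  delta <- c(2, -1, rep(0, 6))
  h <- matrix(rnorm(300 * 8), 300, 8)
  h <- sweep(h, 2, -delta)
  expect_equal(metric_fid(f, h), sum(delta^2), tolerance = 0.5)
  expect_error(metric_fid(f[1, , drop = FALSE], g), "at least 2")
})

test_that("KID is unbiased at the null and grows with separation", {
  # unbiasedness: over fresh same-distribution draws the estimate averages
  # to zero within Monte-Carlo error
  set.seed(44)
  ests <- vapply(1:25, function(s) {
    f <- matrix(rnorm(120 * 6), 120, 6)
    g <- matrix(rnorm(120 * 6), 120, 6)
    metric_kid(f, g, subset_size = 50, n_subsets = 4, seed = s)
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 3 * se)
  # determinism given the seed
  f <- matrix(rnorm(200 * 6), 200, 6)
  g <- matrix(rnorm(200 * 6), 200, 6)
  expect_identical(metric_kid(f, g, seed = 7), metric_kid(f, g, seed = 7))
  # separation grows the estimate monotonically
  k1 <- metric_kid(f, sweep(g, 2, -1), seed = 1)
  k3 <- metric_kid(f, sweep(g, 2, -3), seed = 1)
  expect_gt(k1, 0.01)
  expect_gt(k3, k1)
  expect_error(metric_kid(f, g, subset_size = 1), "subset_size")
})

test_that("the random-projection extractor is deterministic and fixed-d", {
  ex <- feature_extractor_random(d = 64, seed = 20)
  img <- rand_images(1, 16, 16, seed = 45)[[1]]
  v1 <- ex(img)
  expect_length(v1, 64)
  ex2 <- feature_extractor_random(d = 64, seed = 20)
  expect_identical(v1, ex2(img))
})

test_that("evaluate_methods produces a coherent six-metric report", {
  set.seed(46)
  targets <- rand_images(12, 16, 16, seed = 46)
  noisy <- lapply(targets, function(t) {
    pmin(pmax(t + array(rnorm(length(t), sd = 0.05), dim(t)), 0), 1)
  })
  res <- list(
    perfect = list(pred = targets, target = targets),
    noisy = list(pred = noisy, target = targets)
  )
  # small sets against a 64-d extractor: rank-deficiency warnings expected
  rep <- suppressWarnings(
    evaluate_methods(res, kid_subset_size = 8, kid_n_subsets = 4))
  expect_equal(nrow(rep), 2)
  expect_named(rep, c("FID", "KID", "L1", "RMSE", "SSIM", "PSNR"))
  expect_equal(rep["perfect", "L1"], 0)
  expect_equal(rep["perfect", "RMSE"], 0)
  expect_equal(rep["perfect", "SSIM"], 1, tolerance = 1e-9)
  expect_lt(rep["perfect", "FID"], 1e-6)
  expect_equal(unname(attr(rep, "direction")),
               c("down", "down", "down", "down", "up", "up"))
  expect_equal(unname(attr(rep, "best")[["L1"]]), "perfect")
  # mismatched target sets are refused
  res_bad <- res
  res_bad$noisy$target <- rev(targets)
  expect_error(evaluate_methods(res_bad), "different target")
  # export round trip
  pj <- tempfile(fileext = ".json")
  write_metric_report(rep, pj)
  expect_equal(jsonlite::fromJSON(pj)$metrics$L1[1], 0)
})

test_that("spatial and distributional metric families are non-redundant", {
  # construct predictions with correct marginal statistics but shifted
  # content: distribution distances stay small, paired metrics blow up
  set.seed(47)
  targets <- lapply(1:16, function(i) {
    base <- array(0.2, c(16, 16, 3))
    r <- sample(4:12, 1)
    base[r + (-2:2), , ] <- 0.9          # a bright band at a random row
    gaussian_blur(base, 5, 1)
  })
  shifted <- targets[c(9:16, 1:8)]       # same set, wrong pairing
  blurred <- lapply(targets, function(t) {
    array(mean(t), dim(t)) + 0.3 * (t - mean(t))  # paired but flattened
  })
  res <- list(
    shifted = list(pred = shifted, target = targets),
    faded = list(pred = blurred, target = targets)
  )
  rep <- suppressWarnings(
    evaluate_methods(res, kid_subset_size = 10, kid_n_subsets = 4))
  # shifted content: excellent distributional scores, poor paired scores
  expect_lt(rep["shifted", "FID"], 1e-6)
  expect_gt(rep["shifted", "L1"], rep["faded", "L1"])
  # faded content: better paired scores, worse distributional scores
  expect_gt(rep["faded", "FID"], 10 * max(rep["shifted", "FID"], 1e-9))
})
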