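# gradient and brute-force checks of the network primitives

ns <- asNamespace("spectrastain")

test_that("convolution matches a brute-force loop on small tensors", {
  set.seed(21)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  for (stride in 1:2) {
    y <- ns$.cpp_conv_fw(x, w, b, stride, 1L)
    Ho <- dim(y)[1]
    ref <- array(0, dim(y))
    for (bb in 1:2) for (co in 1:3) for (oi in 1:Ho) for (oj in 1:Ho) {
      acc <- b[co]
      for (ci in 1:2) for (ki in 0:2) for (kj in 0:2) {
        ii <- (oi - 1) * stride + ki
        jj <- (oj - 1) * stride + kj
        if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 6) {
          acc <- acc + x[ii, jj, ci, bb] * w[ki + 1, kj + 1, ci, co]
        }
      }
      ref[oi, oj, co, bb] <- acc
    }
    expect_equal(y, ref, tolerance = 1e-5)
  }
})

test_that("generator backpropagation matches finite differences", {
  set.seed(22)
  cfg <- generator_config(4, depth = 2, base_width = 4)
  G <- build_generator(cfg, seed = 3)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  tgt <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  fw <- ns$gen_forward(G, x, keep_cache = TRUE)
  bk <- ns$gen_backward(G, fw$caches, tgt)     # d(sum(y*tgt))/dtheta
  loss <- function(Gm, xx = x) sum(ns$gen_forward(Gm, xx) * tgt)
  # single-coordinate probes on the largest-gradient weights: the
  # convolutions run in single precision and batch-norm gives the loss
  # surface high curvature, so individual probes can be a few percent off;
  # a structural backprop error would miss on every coordinate, hence the
  # median criterion
  eps <- 1e-3
  rels <- c()
  for (nm in c("enc0", "down1", "up2", "out")) {
    W <- G$layers[[nm]]$W
    g <- bk$grads[[nm]]$W
    for (i in order(-abs(g))[1:3]) {
      Gp <- G
      Gp$layers[[nm]]$W[i] <- W[i] + eps
      Gm_ <- G
      Gm_$layers[[nm]]$W[i] <- W[i] - eps
      num <- (loss(Gp) - loss(Gm_)) / (2 * eps)
      rels <- c(rels, abs(num - g[i]) / abs(g[i]))
    }
  }
  expect_lt(median(rels), 0.01)
  expect_lt(max(rels), 0.15)
  # input gradient on the largest-gradient pixels
  relx <- vapply(order(-abs(bk$dx))[1:5], function(i) {
    xp <- x
    xp[i] <- x[i] + eps
    xm <- x
    xm[i] <- x[i] - eps
    num <- (loss(G, xp) - loss(G, xm)) / (2 * eps)
    abs(num - bk$dx[i]) / abs(bk$dx[i])
  }, numeric(1))
  expect_lt(max(relx), 0.05)
})

test_that("discriminator conditions on input and candidate jointly", {
  set.seed(23)
  cfg <- generator_config(4, depth = 2, base_width = 4)
  D <- build_discriminator(cfg, seed = 5)
  x <- array(rnorm(16 * 16 * 4 * 1), c(16, 16, 4, 1))
  cand <- array(rnorm(16 * 16 * 3 * 1), c(16, 16, 3, 1))
  lg <- ns$disc_forward(D, x, cand)
  # patch grid is strictly smaller than the input image
  expect_true(all(dim(lg)[1:2] < 16))
  expect_equal(dim(lg)[3], 1)
  # logits respond to the candidate, not only the input
  cand2 <- cand
  cand2[1:8, 1:8, , ] <- cand2[1:8, 1:8, , ] + 2
  expect_false(isTRUE(all.equal(lg, ns$disc_forward(D, x, cand2))))
  # candidate gradient from the discriminator matches finite differences
  fw <- ns$disc_forward(D, x, cand, keep_cache = TRUE)
  dl <- array(rnorm(length(fw$logits)), dim(fw$logits))
  bk <- ns$disc_backward(D, fw$caches, dl)
  eps <- 0.05
  dirc <- array(rnorm(length(cand)), dim(cand))
  dirc <- dirc / sqrt(sum(dirc^2))
  num <- (sum(ns$disc_forward(D, x, cand + eps * dirc) * dl) -
            sum(ns$disc_forward(D, x, cand - eps * dirc) * dl)) / (2 * eps)
  expect_equal(sum(bk$d_candidate * dirc), num, tolerance = 0.02)
})

test_that("model builds are seed-deterministic and shape-correct", {
  cfg <- generator_config(5, preset = "tiny")
  g1 <- build_generator(cfg, seed = 7)
  g2 <- build_generator(cfg, seed = 7)
  expect_identical(g1$layers, g2$layers)
  g3 <- build_generator(cfg, seed = 8)
  expect_false(identical(g1$layers$enc0$W, g3$layers$enc0$W))
  x <- array(rnorm(64 * 64 * 5), c(64, 64, 5, 1))
  y <- ns$gen_forward(g1, x)
  expect_equal(dim(y), c(64, 64, 3, 1))
  # channel-count generality across the sweep the comparison uses
  for (ch in c(1, 3, 5, 10, 40)) {
    cfgc <- generator_config(ch, depth = 2, base_width = 4)
    gc <- build_generator(cfgc, seed = 1)
    xc <- array(rnorm(16 * 16 * ch), c(16, 16, ch, 1))
    expect_equal(dim(ns$gen_forward(gc, xc)), c(16, 16, 3, 1))
  }
})

test_that("upsampling adjoint agrees with its forward operator", {
  set.seed(24)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  y <- ns$.cpp_up2_fw(x)
  expect_equal(dim(y), c(8, 8, 2, 2))
  expect_equal(y[1, 1, 1, 1], x[1, 1, 1, 1])
  expect_equal(y[2, 2, 1, 1], x[1, 1, 1, 1])
  # adjoint identity <up(x), z> == <x, up^T(z)>
  z <- array(rnorm(length(y)), dim(y))
  expect_equal(sum(y * z), sum(x * ns$.cpp_up2_bw(z)), tolerance = 1e-10)
})

test_that("batch normalization normalizes and backpropagates exactly", {
  set.seed(25)
  x <- array(rnorm(5 * 5 * 3 * 4, mean = 2, sd = 3), c(5, 5, 3, 4))
  fw <- ns$.cpp_bn_fw(x, gamma = c(1, 2, 0.5), beta = c(0, 1, -1), 1e-5)
  for (c in 1:3) {
    expect_equal(mean(fw$xhat[, , c, ]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(as.numeric(fw$xhat[, , c, ])), 1,
                 tolerance = 1e-2)
  }
  expect_equal(mean(fw$y[, , 2, ]), 1, tolerance = 1e-10)
  # gradient check through the normalization statistics
  g <- c(1.2, 0.7, 1.5)
  be <- c(0.1, -0.2, 0)
  dy <- array(rnorm(length(x)), dim(x))
  fw2 <- ns$.cpp_bn_fw(x, g, be, 1e-5)
  bk <- ns$.cpp_bn_bw(fw2$xhat, fw2$invstd, g, dy)
  eps <- 1e-5
  i <- 123
  xp <- x
  xp[i] <- x[i] + eps
  xm <- x
  xm[i] <- x[i] - eps
  num <- (sum(ns$.cpp_bn_fw(xp, g, be, 1e-5)$y * dy) -
            sum(ns$.cpp_bn_fw(xm, g, be, 1e-5)$y * dy)) / (2 * eps)
  expect_equal(bk$dx[i], num, tolerance = 1e-4)
})
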