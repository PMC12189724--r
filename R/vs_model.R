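#' Generator (U-Net) configuration
#'
#' The generator is an encoder-decoder U-Net with skip connections: 3 x 3
#' convolutions throughout, batch normalization and LeakyReLU (negative slope
#' 0.1) after every convolution, stride-2 convolutions for downsampling and
#' nearest-neighbour upsampling in the decoder. `depth` is the number of
#' halvings, so input height and width must be divisible by `2^depth`.
#' `preset = "tiny"` (depth 3, base width 16) is sized for CPU-scale
#' experiments; `"default"` (depth 4, base width 64) mirrors a full-scale
#' image-translation generator.
#'
#' @param in_channels Input channels: number of PCA components, 3 for RGB
#'   reduction, or the full spectral dimension (e.g. 40).
#' @param preset `"tiny"` or `"default"`.
#' @param depth,base_width Override the preset.
#' @param out_channels Output channels (3 for RGB).
#' @param leaky_slope LeakyReLU negative slope.
#' @return A `generator_config`.
#' @export
generator_config <- function(in_channels, preset = c("tiny", "default"),
                             depth = NULL, base_width = NULL,
                             out_channels = 3, leaky_slope = 0.1) {
  preset <- match.arg(preset)
  if (is.null(depth)) depth <- if (preset == "tiny") 3L else 4L
  if (is.null(base_width)) base_width <- if (preset == "tiny") 16L else 64L
  stopifnot(in_channels >= 1, depth >= 1, base_width >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 kernel = 3L, leaky_slope = leaky_slope),
            class = "generator_config")
}

#' Loss configuration for the conditional GAN
#'
#' The generator objective combines a non-saturating adversarial term with a
#' structural similarity term, the L1 distance between Gaussian-blurred
#' generated and target images weighted by `gamma1 = 500`, and a
#' total-variation smoothness term weighted by `gamma2 = 1e-4`. The blur
#' (kernel 5 x 5) de-emphasizes pixel noise in favour of structure.
#'
#' @param gamma1 Blurred-L1 weight (default 500).
#' @param gamma2 Total-variation weight (default 1e-4).
#' @param blur_kernel Odd blur kernel size (default 5).
#' @param blur_sigma Blur standard deviation in pixels (default 1).
#' @return A `loss_config`.
#' @export
loss_config <- function(gamma1 = 500, gamma2 = 1e-4, blur_kernel = 5,
                        blur_sigma = 1) {
  stopifnot(gamma1 >= 0, gamma2 >= 0, blur_sigma > 0)
  if (blur_kernel %% 2 != 1) stop("blur_kernel must be odd", call. = FALSE)
  structure(list(gamma1 = gamma1, gamma2 = gamma2,
                 blur_kernel = as.integer(blur_kernel),
                 blur_sigma = blur_sigma),
            class = "loss_config")
}

#' Training configuration
#'
#' Adam optimization with the staircase learning-rate schedule
#' `lr * decay^(epoch %/% decay_every)`: the rate starts at 0.02 and is
#' multiplied by 0.85 every five epochs (so epoch 10 trains at
#' 0.02 x 0.85^2 = 0.01445).
#'
#' @param epochs Training epochs (default 100).
#' @param lr Initial learning rate (default 0.02).
#' @param lr_decay Multiplicative decay factor (default 0.85).
#' @param decay_every Epoch interval between decays (default 5).
#' @param batch_size Minibatch size (default 8).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 100, lr = 0.02, lr_decay = 0.85,
                         decay_every = 5, batch_size = 8, seed = 1) {
  stopifnot(epochs >= 1, lr > 0, lr_decay > 0, lr_decay <= 1,
            decay_every >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' @param cfg A [train_config()].
#' @param epoch 1-based epoch index.
#' @return The learning rate in effect during `epoch`.
#' @examples
#' lr_at_epoch(train_config(), 10)  # 0.01445
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay^(epoch %/% cfg$decay_every)
}

# --- normalization --------------------------------------------------------

#' Per-channel normalization statistics
#'
#' Computes the per-channel mean and standard deviation over a list of
#' H x W x C arrays (the training split), used to centre and scale each
#' channel separately. Statistics must come from the training split only so
#' no information leaks from held-out data.
#'
#' @param arrays List of H x W x C numeric arrays.
#' @return List with `mean` and `sd` vectors of length C.
#' @export
channel_stats <- function(arrays) {
  cc <- dim(arrays[[1]])[3]
  acc_n <- 0
  acc_s <- numeric(cc)
  acc_s2 <- numeric(cc)
  for (a in arrays) {
    m <- matrix(a, ncol = cc)
    acc_n <- acc_n + nrow(m)
    acc_s <- acc_s + colSums(m)
    acc_s2 <- acc_s2 + colSums(m^2)
  }
  mu <- acc_s / acc_n
  sd <- sqrt(pmax(acc_s2 / acc_n - mu^2, 0) * acc_n / (acc_n - 1))
  list(mean = mu, sd = sd)
}

#' Normalize or denormalize per channel
#'
#' Applies `(x - mean) / sd` channelwise (or the inverse). A channel with
#' (near-)zero standard deviation raises an error, since it cannot be
#' scaled meaningfully.
#'
#' @param x H x W x C array or H x W x C x B batch.
#' @param stats From [channel_stats()].
#' @param invert Apply the inverse transform.
#' @return Array of the same shape.
#' @export
normalize_channels <- function(x, stats, invert = FALSE) {
  if (any(stats$sd < 1e-10)) {
    stop("degenerate channel: zero standard deviation", call. = FALSE)
  }
  d <- dim(x)
  cdim <- 3L
  per <- prod(d[seq_len(cdim - 1)])
  rep_each <- rep(seq_len(d[cdim]), each = per)
  if (length(d) == 4) rep_each <- rep(rep_each, d[4])
  if (invert) {
    array(as.numeric(x) * stats$sd[rep_each] + stats$mean[rep_each], d)
  } else {
    array((as.numeric(x) - stats$mean[rep_each]) / stats$sd[rep_each], d)
  }
}

# --- blur and total variation --------------------------------------------

blur_op_cache <- new.env(parent = emptyenv())

# n x n 1-D convolution operator with reflect padding; kernel sums to 1
make_blur_op <- function(n, kernel, sigma) {
  key <- paste(n, kernel, sigma, sep = "_")
  if (!is.null(blur_op_cache[[key]])) return(blur_op_cache[[key]])
  r <- (kernel - 1) / 2
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (t in seq(-r, r)) {
      j <- i + t
      if (j < 1) j <- 1 - j + 1      # reflect (edge mirrored without repeat)
      if (j > n) j <- 2 * n - j + 1
      A[i, j] <- A[i, j] + k[t + r + 1]
    }
  }
  blur_op_cache[[key]] <- A
  A
}

#' Gaussian blur of an image
#'
#' Separable Gaussian convolution with reflect padding; the kernel is
#' normalized to sum to 1, so constant images are unchanged.
#'
#' @param img H x W, H x W x C array or H x W x C x B batch.
#' @param kernel Odd kernel size (default 5).
#' @param sigma Standard deviation in pixels (default 1).
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(img, kernel = 5, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (kernel %% 2 != 1) stop("kernel must be odd", call. = FALSE)
  d <- dim(img)
  if (is.null(d)) stop("img must be a matrix or array", call. = FALSE)
  A <- make_blur_op(d[1], kernel, sigma)
  B <- make_blur_op(d[2], kernel, sigma)
  if (length(d) == 2) return(A %*% img %*% t(B))
  out <- img
  idx <- expand.grid(c = seq_len(d[3]),
                     b = if (length(d) == 4) seq_len(d[4]) else 1)
  for (r in seq_len(nrow(idx))) {
    if (length(d) == 4) {
      out[, , idx$c[r], idx$b[r]] <-
        A %*% img[, , idx$c[r], idx$b[r]] %*% t(B)
    } else {
      out[, , idx$c[r]] <- A %*% img[, , idx$c[r]] %*% t(B)
    }
  }
  out
}

# adjoint of gaussian_blur (transposed operators), for backprop
gaussian_blur_adjoint <- function(img, kernel = 5, sigma = 1) {
  d <- dim(img)
  A <- t(make_blur_op(d[1], kernel, sigma))
  B <- make_blur_op(d[2], kernel, sigma)
  out <- img
  idx <- expand.grid(c = seq_len(d[3]),
                     b = if (length(d) == 4) seq_len(d[4]) else 1)
  for (r in seq_len(nrow(idx))) {
    if (length(d) == 4) {
      out[, , idx$c[r], idx$b[r]] <- A %*% img[, , idx$c[r], idx$b[r]] %*% B
    } else {
      out[, , idx$c[r]] <- A %*% img[, , idx$c[r]] %*% B
    }
  }
  out
}

#' Anisotropic squared total variation
#'
#' `TV(x) = sum_c sum_{i<H} (x[i,j,c]-x[i+1,j,c])^2 + sum_{j<W}
#' (x[i,j,c]-x[i,j+1,c])^2`: the sum of squared differences between
#' vertically and horizontally adjacent pixels over all channels. Penalizing
#' it favours smooth, coherent images.
#'
#' @param img H x W x C array (C = 3 for RGB).
#' @return Non-negative scalar.
#' @examples
#' img <- array(0, c(2, 2, 3)); img[, , 1] <- c(0, 0, 1, 1)
#' total_variation(img)  # 2
#' @export
total_variation <- function(img) {
  d <- dim(img)
  stopifnot(length(d) == 3)
  dv <- img[-d[1], , , drop = FALSE] - img[-1, , , drop = FALSE]
  dh <- img[, -d[2], , drop = FALSE] - img[, -1, , drop = FALSE]
  sum(dv^2) + sum(dh^2)
}

# gradient of total_variation wrt the image (per image in a batch)
tv_grad <- function(img) {
  d <- dim(img)
  g <- array(0, d)
  dv <- img[-d[1], , , drop = FALSE] - img[-1, , , drop = FALSE]
  dh <- img[, -d[2], , drop = FALSE] - img[, -1, , drop = FALSE]
  g[-d[1], , ] <- g[-d[1], , , drop = FALSE] + 2 * dv
  g[-1, , ] <- g[-1, , , drop = FALSE] - 2 * dv
  g[, -d[2], ] <- g[, -d[2], , drop = FALSE] + 2 * dh
  g[, -1, ] <- g[, -1, , drop = FALSE] - 2 * dh
  g
}

# --- loss functions -------------------------------------------------------

check_prob <- function(p, what) {
  if (any(p <= 0) || any(p >= 1)) {
    stop(sprintf("%s must lie strictly inside (0, 1)", what), call. = FALSE)
  }
  p
}

#' Generator loss
#'
#' Non-saturating adversarial term `-mean(log d_out)` plus
#' `gamma1 * mean(|blur(gen) - blur(target)|)` plus
#' `gamma2 * TV(gen)`. The L1 term uses the mean over pixels and channels so
#' `gamma1 = 500` is stable across patch sizes. When the generated image
#' equals the target and the discriminator is fully fooled, all three terms
#' vanish.
#'
#' @param d_out Discriminator probabilities for the generated image (scalar
#'   or patch grid), strictly inside (0, 1).
#' @param gen_img,target_img H x W x 3 images of identical shape.
#' @param cfg A [loss_config()].
#' @return List with `total`, `adversarial`, `l1`, `tv`.
#' @export
generator_loss <- function(d_out, gen_img, target_img, cfg = loss_config()) {
  stopifnot(identical(dim(gen_img), dim(target_img)))
  check_prob(d_out, "d_out")
  adv <- -mean(log(d_out))
  bg <- gaussian_blur(gen_img, cfg$blur_kernel, cfg$blur_sigma)
  bt <- gaussian_blur(target_img, cfg$blur_kernel, cfg$blur_sigma)
  l1 <- mean(abs(bg - bt))
  tv <- total_variation(gen_img)
  list(total = adv + cfg$gamma1 * l1 + cfg$gamma2 * tv,
       adversarial = adv, l1 = l1, tv = tv)
}

#' Discriminator loss
#'
#' Standard conditional-GAN discriminator objective
#' `-0.5 * (mean(log d_real) + mean(log(1 - d_fake)))`, averaged over patch
#' outputs. It is minimized by `d_real -> 1`, `d_fake -> 0`; at the
#' uninformative point `d_real = d_fake = 0.5` it equals `log 2`.
#'
#' @param d_real,d_fake Discriminator probabilities on real and generated
#'   pairs, strictly inside (0, 1).
#' @return Scalar loss.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  check_prob(d_real, "d_real")
  check_prob(d_fake, "d_fake")
  -0.5 * (mean(log(d_real)) + mean(log(1 - d_fake)))
}

# --- model construction ---------------------------------------------------

#' Build generator / discriminator parameter sets
#'
#' Creates randomly initialized (He-normal, seed-deterministic) parameter
#' structures. The generator is the U-Net described in
#' [generator_config()]; the discriminator is a patch classifier: three
#' stride-2 3 x 3 convolution blocks (LeakyReLU throughout, batch
#' normalization except on the first), then a 3 x 3 convolution to a 1-channel
#' logit grid whose cells rate overlapping local patches as real or fake. The
#' discriminator sees the input representation and the candidate output
#' concatenated along channels.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed for the initial weights.
#' @return A model handle (list of layer parameter arrays plus config).
#' @export
build_generator <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  w <- cfg$base_width
  layers <- list()
  layers$enc0 <- init_block(3, 3, cfg$in_channels, w)
  for (l in seq_len(cfg$depth)) {
    layers[[paste0("down", l)]] <- init_block(3, 3, w * 2^(l - 1), w * 2^l)
  }
  wd <- w * 2^cfg$depth
  layers$bottleneck <- init_block(3, 3, wd, wd)
  for (l in rev(seq_len(cfg$depth))) {
    layers[[paste0("up", l)]] <-
      init_block(3, 3, w * 2^l + w * 2^(l - 1), w * 2^(l - 1))
  }
  layers$out <- init_conv(3, 3, w, cfg$out_channels)
  structure(list(cfg = cfg, layers = layers), class = "vs_generator")
}

#' @rdname build_generator
#' @export
build_discriminator <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed + 1L)
  w <- cfg$base_width
  cin <- cfg$in_channels + cfg$out_channels
  layers <- list(
    d1 = init_block(3, 3, cin, w, bn = FALSE),
    d2 = init_block(3, 3, w, 2 * w),
    d3 = init_block(3, 3, 2 * w, 4 * w),
    dout = init_conv(3, 3, 4 * w, 1)
  )
  structure(list(cfg = cfg, layers = layers), class = "vs_discriminator")
}

# --- forward / backward passes -------------------------------------------

gen_forward <- function(G, x, keep_cache = FALSE) {
  cfg <- G$cfg
  s <- cfg$leaky_slope
  L <- G$layers
  caches <- list()
  enc <- list()
  r <- block_fw(L$enc0, x, stride = 1, slope = s)
  caches$enc0 <- r$cache
  enc[[1]] <- r$y
  h <- r$y
  for (l in seq_len(cfg$depth)) {
    r <- block_fw(L[[paste0("down", l)]], h, stride = 2, slope = s)
    caches[[paste0("down", l)]] <- r$cache
    enc[[l + 1]] <- r$y
    h <- r$y
  }
  r <- block_fw(L$bottleneck, h, stride = 1, slope = s)
  caches$bottleneck <- r$cache
  h <- r$y
  for (l in rev(seq_len(cfg$depth))) {
    hu <- .cpp_up2_fw(h)
    hc <- cat_ch(hu, enc[[l]])
    r <- block_fw(L[[paste0("up", l)]], hc, stride = 1, slope = s)
    caches[[paste0("up", l)]] <- r$cache
    h <- r$y
  }
  y <- .cpp_conv_fw(h, L$out$W, L$out$b, 1L, 1L)
  caches$out_in <- h
  if (keep_cache) list(y = y, caches = caches) else y
}

gen_backward <- function(G, caches, dy) {
  cfg <- G$cfg
  s <- cfg$leaky_slope
  L <- G$layers
  grads <- list()
  cv <- .cpp_conv_bw(caches$out_in, L$out$W, dy, 1L, 1L)
  grads$out <- list(W = cv$dw, b = as.numeric(cv$db))
  dh <- cv$dx
  dskip <- list()
  for (l in seq_len(cfg$depth)) {
    r <- block_bw(L[[paste0("up", l)]], caches[[paste0("up", l)]], dh,
                  slope = s)
    grads[[paste0("up", l)]] <- r$grads
    nup <- cfg$base_width * 2^l
    sp <- split_ch(r$dx, nup)
    dskip[[l]] <- sp$b
    dh <- .cpp_up2_bw(sp$a)
  }
  r <- block_bw(L$bottleneck, caches$bottleneck, dh, slope = s)
  grads$bottleneck <- r$grads
  dh <- r$dx
  for (l in rev(seq_len(cfg$depth))) {
    if (l < cfg$depth) dh <- dh + dskip[[l + 1]]
    r <- block_bw(L[[paste0("down", l)]], caches[[paste0("down", l)]], dh,
                  slope = s)
    grads[[paste0("down", l)]] <- r$grads
    dh <- r$dx
  }
  dh <- dh + dskip[[1]]
  r <- block_bw(L$enc0, caches$enc0, dh, slope = s)
  grads$enc0 <- r$grads
  list(dx = r$dx, grads = grads)
}

disc_forward <- function(D, x, candidate, keep_cache = FALSE) {
  s <- D$cfg$leaky_slope
  L <- D$layers
  xc <- cat_ch(x, candidate)
  caches <- list(n_input = dim(x)[3])
  r1 <- block_fw(L$d1, xc, stride = 2, slope = s)
  caches$d1 <- r1$cache
  r2 <- block_fw(L$d2, r1$y, stride = 2, slope = s)
  caches$d2 <- r2$cache
  r3 <- block_fw(L$d3, r2$y, stride = 2, slope = s)
  caches$d3 <- r3$cache
  logits <- .cpp_conv_fw(r3$y, L$dout$W, L$dout$b, 1L, 1L)
  caches$dout_in <- r3$y
  if (keep_cache) list(logits = logits, caches = caches) else logits
}

# returns gradients for D parameters and for the candidate image channels
disc_backward <- function(D, caches, dlogits) {
  s <- D$cfg$leaky_slope
  L <- D$layers
  grads <- list()
  cv <- .cpp_conv_bw(caches$dout_in, L$dout$W, dlogits, 1L, 1L)
  grads$dout <- list(W = cv$dw, b = as.numeric(cv$db))
  r <- block_bw(L$d3, caches$d3, cv$dx, slope = s)
  grads$d3 <- r$grads
  r <- block_bw(L$d2, caches$d2, r$dx, slope = s)
  grads$d2 <- r$grads
  r <- block_bw(L$d1, caches$d1, r$dx, slope = s)
  grads$d1 <- r$grads
  sp <- split_ch(r$dx, caches$n_input)
  list(grads = grads, d_candidate = sp$b, d_input = sp$a)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
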