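# Internal layer plumbing for the conditional GAN. Tensors are numeric 4-D
# arrays (H, W, C, B); the heavy kernels live in src/nn_ops.cpp.

as_batch <- function(x) {
  if (length(dim(x)) == 3) {
    array(x, c(dim(x), 1))
  } else x
}

cat_ch <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(x, n_first) {
  d <- dim(x)
  list(a = x[, , seq_len(n_first), , drop = FALSE],
       b = x[, , (n_first + 1):d[3], , drop = FALSE])
}

init_conv <- function(kh, kw, cin, cout) {
  # He-normal fan-in initialization
  sd <- sqrt(2 / (kh * kw * cin))
  list(W = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_block <- function(kh, kw, cin, cout, bn = TRUE) {
  p <- init_conv(kh, kw, cin, cout)
  if (bn) {
    p$gamma <- rep(1, cout)
    p$beta <- numeric(cout)
  }
  p
}

# conv [+ batchnorm] [+ leaky relu] block
block_fw <- function(p, x, stride = 1L, pad = 1L, slope = 0.1,
                     act = TRUE) {
  y <- .cpp_conv_fw(x, p$W, p$b, as.integer(stride), as.integer(pad))
  cache <- list(x = x, stride = stride, pad = pad)
  if (!is.null(p$gamma)) {
    bn <- .cpp_bn_fw(y, p$gamma, p$beta, 1e-5)
    cache$xhat <- bn$xhat
    cache$invstd <- bn$invstd
    y <- bn$y
  }
  if (act) {
    cache$pre_act <- y
    y <- .cpp_lrelu_fw(y, slope)
  }
  list(y = y, cache = cache)
}

block_bw <- function(p, cache, dy, slope = 0.1) {
  if (!is.null(cache$pre_act)) {
    dy <- .cpp_lrelu_bw(cache$pre_act, dy, slope)
  }
  g <- list()
  if (!is.null(p$gamma)) {
    bn <- .cpp_bn_bw(cache$xhat, cache$invstd, p$gamma, dy)
    dy <- bn$dx
    g$gamma <- as.numeric(bn$dgamma)
    g$beta <- as.numeric(bn$dbeta)
  }
  cv <- .cpp_conv_bw(cache$x, p$W, dy, as.integer(cache$stride),
                     as.integer(cache$pad))
  g$W <- cv$dw
  g$b <- as.numeric(cv$db)
  list(dx = cv$dx, grads = g)
}

# --- Adam over nested parameter lists -------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0), how = "list")
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p) && !is.numeric(p)) {
      out_p <- p
      out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p
        out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      m <- beta1 * s$m + (1 - beta1) * g
      v <- beta2 * s$v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
    }
  }
  walk(params, grads, state)
}

# leaf-level check distinguishing parameter arrays from nested lists
is_param_leaf <- function(x) is.numeric(x)
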