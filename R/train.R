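# softplus with overflow guard: log(1 + exp(z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

assemble_batch <- function(items, field, idx) {
  d <- dim(items[[idx[1]]][[field]])
  out <- array(0, c(d[1], d[2], d[3], length(idx)))
  for (k in seq_along(idx)) out[, , , k] <- items[[idx[k]]][[field]]
  out
}

#' Train the virtual-staining conditional GAN
#'
#' Alternating generator/discriminator optimization with Adam and the
#' staircase learning-rate schedule of [train_config()]. Inputs and targets
#' are normalized channelwise with statistics of the training split. The
#' discriminator minimizes the patch-averaged real/fake cross-entropy
#' ([discriminator_loss()]); the generator minimizes the non-saturating
#' adversarial term plus the weighted blurred-L1 and total-variation terms
#' ([generator_loss()]), both implemented on logits for numerical stability.
#' After every epoch the blurred-L1 term is evaluated on held-out patches
#' (in normalized target space), giving a leakage-free convergence trace.
#'
#' A non-finite loss aborts training with a condition of class
#' `"vs_divergence_error"` carrying the last finite-state checkpoint in its
#' `checkpoint` field.
#'
#' @param dataset A [build_dataset()] output passed through
#'   [prepare_inputs()] (every patch needs `input` and `target`).
#' @param gen_cfg A [generator_config()]; defaults to the `"tiny"` preset
#'   with `in_channels` taken from the data.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param heldout_max Maximum held-out patches used for the per-epoch trace.
#' @param verbose Print a line per epoch.
#' @return A `vs_checkpoint`: generator and discriminator parameters,
#'   configs, normalization statistics and a per-epoch `history` data.frame
#'   (columns `epoch`, `lr`, `loss_d`, `loss_g`, `loss_g_adv`, `loss_g_l1`,
#'   `loss_g_tv`, `heldout_l1`).
#' @export
vs_train <- function(dataset, gen_cfg = NULL, loss_cfg = loss_config(),
                     train_cfg = train_config(), heldout_max = 32,
                     verbose = FALSE) {
  stopifnot(inherits(dataset, "vs_dataset"))
  train <- dataset$train
  if (!length(train) || is.null(train[[1]]$input)) {
    stop("dataset has no prepared inputs; call prepare_inputs() first",
         call. = FALSE)
  }
  in_ch <- dim(train[[1]]$input)[3]
  if (is.null(gen_cfg)) gen_cfg <- generator_config(in_ch, preset = "tiny")
  if (gen_cfg$in_channels != in_ch) {
    stop("gen_cfg$in_channels does not match the data", call. = FALSE)
  }
  hwd <- dim(train[[1]]$input)[1:2]
  if (any(hwd %% 2^gen_cfg$depth != 0)) {
    stop("patch size must be divisible by 2^depth", call. = FALSE)
  }

  stats_in <- channel_stats(lapply(train, `[[`, "input"))
  stats_out <- channel_stats(lapply(train, `[[`, "target"))
  norm_in <- lapply(train, function(p) normalize_channels(p$input, stats_in))
  norm_out <- lapply(train, function(p) normalize_channels(p$target,
                                                           stats_out))
  items <- Map(function(i, o) list(input = i, target = o), norm_in, norm_out)

  heldout <- utils::head(dataset$test, heldout_max)
  ho_in <- lapply(heldout, function(p) normalize_channels(p$input, stats_in))
  ho_out <- lapply(heldout, function(p) normalize_channels(p$target,
                                                           stats_out))

  G <- build_generator(gen_cfg, seed = train_cfg$seed)
  D <- build_discriminator(gen_cfg, seed = train_cfg$seed)
  sg <- adam_init(G$layers)
  sd_ <- adam_init(D$layers)
  set.seed(train_cfg$seed + 2L)

  nb <- length(items)
  bs <- min(train_cfg$batch_size, nb)
  hist <- list()
  t_g <- 0L
  t_d <- 0L
  last_good <- NULL
  g1 <- loss_cfg$gamma1
  g2 <- loss_cfg$gamma2
  bk <- loss_cfg$blur_kernel
  bsig <- loss_cfg$blur_sigma

  heldout_l1 <- function() {
    if (!length(ho_in)) return(NA_real_)
    tot <- 0
    n <- 0
    i <- 1
    while (i <= length(ho_in)) {
      j <- min(i + bs - 1, length(ho_in))
      x <- simplify2array(ho_in[i:j])
      y <- simplify2array(ho_out[i:j])
      if (length(dim(x)) == 3) {
        dim(x) <- c(dim(x), 1)
        dim(y) <- c(dim(y), 1)
      }
      fake <- gen_forward(G, x)
      bd <- gaussian_blur(fake, bk, bsig) - gaussian_blur(y, bk, bsig)
      tot <- tot + sum(abs(bd))
      n <- n + length(bd)
      i <- j + 1
    }
    tot / n
  }

  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- lr_at_epoch(train_cfg, epoch)
    ord <- sample.int(nb)
    ep <- c(loss_d = 0, loss_g = 0, adv = 0, l1 = 0, tv = 0, nsteps = 0)
    for (start in seq(1, nb, by = bs)) {
      idx <- ord[start:min(start + bs - 1, nb)]
      x <- assemble_batch(items, "input", idx)
      y <- assemble_batch(items, "target", idx)
      B <- length(idx)

      gf <- gen_forward(G, x, keep_cache = TRUE)
      fake <- gf$y

      ## ---- discriminator update ----
      fr <- disc_forward(D, x, y, keep_cache = TRUE)
      ff <- disc_forward(D, x, fake, keep_cache = TRUE)
      P <- length(fr$logits)
      loss_d <- 0.5 * (mean(softplus(-fr$logits)) +
                         mean(softplus(ff$logits)))
      dlr <- -(1 - sigmoid(fr$logits)) / (2 * P)
      dlf <- sigmoid(ff$logits) / (2 * P)
      br <- disc_backward(D, fr$caches, array(dlr, dim(fr$logits)))
      bf <- disc_backward(D, ff$caches, array(dlf, dim(ff$logits)))
      gd <- Map(function(a, b) Map(`+`, a, b), br$grads, bf$grads)
      t_d <- t_d + 1L
      up <- adam_update(D$layers, gd, sd_, lr, t_d)
      D$layers <- up$p
      sd_ <- up$s

      ## ---- generator update ----
      fg <- disc_forward(D, x, fake, keep_cache = TRUE)
      P2 <- length(fg$logits)
      adv <- mean(softplus(-fg$logits))
      dl <- -(1 - sigmoid(fg$logits)) / P2
      db <- disc_backward(D, fg$caches, array(dl, dim(fg$logits)))
      dfake <- db$d_candidate

      bg <- gaussian_blur(fake, bk, bsig)
      bt <- gaussian_blur(y, bk, bsig)
      l1 <- mean(abs(bg - bt))
      dfake <- dfake + g1 *
        gaussian_blur_adjoint(array(sign(bg - bt) / length(bg), dim(bg)),
                              bk, bsig)
      tv <- 0
      for (b in seq_len(B)) {
        img <- array(fake[, , , b], dim(fake)[1:3])
        tv <- tv + total_variation(img) / B
        dfake[, , , b] <- dfake[, , , b] + g2 * tv_grad(img) / B
      }
      loss_g <- adv + g1 * l1 + g2 * tv
      gb <- gen_backward(G, gf$caches, dfake)
      t_g <- t_g + 1L
      up <- adam_update(G$layers, gb$grads, sg, lr, t_g)
      G$layers <- up$p
      sg <- up$s

      if (!all(is.finite(c(loss_d, loss_g)))) {
        cond <- structure(
          class = c("vs_divergence_error", "error", "condition"),
          list(message = sprintf("non-finite loss at epoch %d", epoch),
               call = sys.call(-1), checkpoint = last_good))
        stop(cond)
      }
      ep <- ep + c(loss_d, loss_g, adv, l1, tv, 1)
    }
    ns <- ep[["nsteps"]]
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, loss_d = ep[["loss_d"]] / ns,
      loss_g = ep[["loss_g"]] / ns, loss_g_adv = ep[["adv"]] / ns,
      loss_g_l1 = ep[["l1"]] / ns, loss_g_tv = ep[["tv"]] / ns,
      heldout_l1 = heldout_l1())
    last_good <- list(generator = G, discriminator = D, gen_cfg = gen_cfg,
                      loss_cfg = loss_cfg, train_cfg = train_cfg,
                      stats_input = stats_in, stats_target = stats_out,
                      method = dataset$method, basis = dataset$basis,
                      history = do.call(rbind, hist))
    if (verbose) {
      message(sprintf(
        "epoch %3d lr %.5f  D %.4f  G %.3f (l1 %.4f)  heldout-l1 %.4f",
        epoch, lr, hist[[epoch]]$loss_d, hist[[epoch]]$loss_g,
        hist[[epoch]]$loss_g_l1, hist[[epoch]]$heldout_l1))
    }
  }
  structure(last_good, class = "vs_checkpoint")
}

#' @export
print.vs_checkpoint <- function(x, ...) {
  h <- utils::tail(x$history, 1)
  cat(sprintf(
    "<vs_checkpoint> %s input (%d ch), %d epochs, heldout blurred-L1 %.4f\n",
    if (is.null(x$method)) "?" else x$method, x$gen_cfg$in_channels,
    h$epoch, h$heldout_l1))
  invisible(x)
}

#' Virtually stain an input representation
#'
#' Runs the trained generator on one input patch (the same representation
#' the checkpoint was trained on: PCA coefficients, RGB reduction or full
#' spectral cube), then undoes the target normalization and clips to [0, 1].
#' Deterministic given checkpoint and input. Normalization layers use the
#' statistics of the presented batch (single image at inference), the usual
#' convention for batch-normalized image-translation generators.
#'
#' @param checkpoint A [vs_train()] result.
#' @param input H x W x C array with C matching the checkpoint, or a
#'   [spectral_cube()] / reduced cube of matching channel count.
#' @return H x W x 3 RGB array in [0, 1].
#' @export
vs_stain <- function(checkpoint, input) {
  stopifnot(inherits(checkpoint, "vs_checkpoint"))
  x <- unclass(input)
  attr(x, "wavelengths") <- NULL
  attr(x, "basis") <- NULL
  if (length(dim(x)) != 3) stop("input must be H x W x C", call. = FALSE)
  if (dim(x)[3] != checkpoint$gen_cfg$in_channels) {
    stop(sprintf("input has %d channels, checkpoint expects %d",
                 dim(x)[3], checkpoint$gen_cfg$in_channels), call. = FALSE)
  }
  xb <- as_batch(normalize_channels(x, checkpoint$stats_input))
  yb <- gen_forward(checkpoint$generator, xb)
  y <- array(yb, dim(yb)[1:3])
  y <- normalize_channels(y, checkpoint$stats_target, invert = TRUE)
  pmin(pmax(y, 0), 1)
}

#' Save / load a checkpoint
#'
#' Serializes the full checkpoint (weights, configs, normalization
#' statistics, history) with R's native serialization, alongside a small
#' JSON header describing the generator configuration.
#'
#' @param checkpoint A `vs_checkpoint`.
#' @param path Output path (`.rds`); a `.json` header is written next to it.
#' @export
write_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "vs_checkpoint"))
  saveRDS(checkpoint, path)
  jsonlite::write_json(checkpoint$gen_cfg[c("in_channels", "out_channels",
                                            "depth", "base_width")],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "vs_checkpoint"))
  ck
}
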