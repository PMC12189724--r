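#' Run a full virtual-staining comparison experiment
#'
#' End-to-end benchmark on phantom data: build a registered
#' unstained/stained paired-patch dataset, train one conditional GAN per
#' input representation (PCA-n coefficients, CIE 1931 RGB reduction, full
#' spectral cube), stain the held-out patches with each model, and score all
#' methods on the common target set with the six-metric report
#' ([evaluate_methods()]). Patients (seed groups) are split between train
#' and test, never within.
#'
#' The defaults are a CPU-scale study: 50 phantom sections of 128 x 128
#' pixels tiled into 200 paired 64 x 64 patches over nine synthetic
#' patients (three held out), the tiny U-Net preset and 20 epochs. The
#' optimizer schedule (Adam, lr 0.02 decayed by 0.85 every 5 epochs) and the
#' loss weights are the package defaults.
#'
#' @param methods Character subset of `"pca"`, `"rgb"`, `"full"`.
#' @param n_components PCA components for the `"pca"` method.
#' @param n_pairs,image_size,patch,stride,n_groups,test_groups,noise_sd,morph_eps
#'   Dataset parameters, see [build_dataset()].
#' @param epochs,batch_size Training schedule, see [train_config()].
#' @param preset Generator preset, see [generator_config()].
#' @param seed Master seed for data, initialization and shuffling.
#' @param verbose Print per-epoch progress.
#' @return A `vs_experiment`: list with `report` (metric_report),
#'   `histories` (per-method training history), `checkpoints`, `dataset`
#'   parameters and `predictions`.
#' @export
vs_experiment <- function(methods = c("pca", "rgb", "full"),
                          n_components = 5, n_pairs = 50, image_size = 128,
                          patch = 64, stride = 64, n_groups = 9,
                          test_groups = 7:9, noise_sd = 0.01,
                          morph_eps = 0, epochs = 20, batch_size = 8,
                          preset = "tiny", seed = 1, verbose = FALSE) {
  methods <- match.arg(methods, c("pca", "rgb", "full"), several.ok = TRUE)
  ds <- build_dataset(n_pairs = n_pairs, image_size = image_size,
                      patch = patch, stride = stride, n_groups = n_groups,
                      test_groups = test_groups, noise_sd = noise_sd,
                      morph_eps = morph_eps, seed = seed)
  label <- c(pca = sprintf("PCA-%d", n_components), rgb = "rRGB",
             full = "Full SI")
  checkpoints <- list()
  histories <- list()
  results <- list()
  targets <- lapply(ds$test, `[[`, "target")
  for (m in methods) {
    if (verbose) message("== training method: ", label[[m]], " ==")
    dsp <- prepare_inputs(ds, m, n_components = n_components)
    ck <- vs_train(dsp,
                   gen_cfg = generator_config(dim(dsp$train[[1]]$input)[3],
                                              preset = preset),
                   train_cfg = train_config(epochs = epochs,
                                            batch_size = batch_size,
                                            seed = seed),
                   verbose = verbose)
    preds <- lapply(dsp$test, function(p) vs_stain(ck, p$input))
    checkpoints[[label[[m]]]] <- ck
    histories[[label[[m]]]] <- ck$history
    results[[label[[m]]]] <- list(pred = preds, target = targets)
  }
  report <- evaluate_methods(results)
  structure(list(report = report, histories = histories,
                 checkpoints = checkpoints,
                 predictions = lapply(results, `[[`, "pred"),
                 targets = targets,
                 params = c(ds$params, list(methods = methods,
                                            n_components = n_components,
                                            epochs = epochs,
                                            preset = preset))),
            class = "vs_experiment")
}

#' @export
print.vs_experiment <- function(x, ...) {
  cat("<vs_experiment>\n")
  for (m in names(x$histories)) {
    h <- x$histories[[m]]
    cat(sprintf("  %-8s heldout blurred-L1: epoch 1 %.4f -> final %.4f (%.0f%% drop)\n",
                m, h$heldout_l1[1], h$heldout_l1[nrow(h)],
                100 * (1 - h$heldout_l1[nrow(h)] / h$heldout_l1[1])))
  }
  print(x$report)
  invisible(x)
}
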