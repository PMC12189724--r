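#' Paired spatial metrics: L1 and RMSE
#'
#' Mean absolute and root-mean-square pixel difference over all pixels and
#' channels of two same-shaped images in [0, 1].
#'
#' @param a,b Numeric arrays of identical shape.
#' @return Non-negative scalar.
#' @export
metric_l1 <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  mean(abs(a - b))
}

#' @rdname metric_l1
#' @export
metric_rmse <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(max_val^2 / MSE)` in dB; identical images return `Inf`.
#'
#' @param a,b Images of identical shape.
#' @param max_val Peak signal value (1 for [0, 1] images).
#' @return PSNR in dB.
#' @export
metric_psnr <- function(a, b, max_val = 1) {
  stopifnot(identical(dim(a), dim(b)))
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' Structural similarity index
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5),
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, computed per channel and averaged
#' over windows and channels. Symmetric in its arguments; `ssim(a, a) = 1`.
#'
#' @param a,b Images (H x W or H x W x C) of identical shape, values in
#'   [0, L].
#' @param max_val Dynamic range L (default 1).
#' @param window Window size (odd, default 11); must not exceed the image.
#' @param sigma Window standard deviation (default 1.5).
#' @return SSIM in [-1, 1].
#' @export
metric_ssim <- function(a, b, max_val = 1, window = 11, sigma = 1.5) {
  stopifnot(identical(dim(a), dim(b)))
  d <- dim(a)
  if (min(d[1:2]) < window) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  c1 <- (0.01 * max_val)^2
  c2 <- (0.03 * max_val)^2
  ssim_plane <- function(x, y) {
    mu_x <- gaussian_blur(x, window, sigma)
    mu_y <- gaussian_blur(y, window, sigma)
    sxx <- gaussian_blur(x * x, window, sigma) - mu_x^2
    syy <- gaussian_blur(y * y, window, sigma) - mu_y^2
    sxy <- gaussian_blur(x * y, window, sigma) - mu_x * mu_y
    num <- (2 * mu_x * mu_y + c1) * (2 * sxy + c2)
    den <- (mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2)
    mean(num / den)
  }
  if (length(d) == 2) return(ssim_plane(a, b))
  mean(vapply(seq_len(d[3]),
              function(c) ssim_plane(a[, , c], b[, , c]), numeric(1)))
}

#' Random-projection feature extractor for FID/KID
#'
#' A deterministic, self-contained image embedding: images are average-pooled
#' to an 8 x 8 x C grid and mapped through a fixed random Gaussian projection
#' to `d` dimensions. It captures colour and coarse spatial statistics,
#' making distribution distances sensitive to the same departures a deep
#' extractor would flag at this image scale, while requiring no pretrained
#' network. Any function mapping an image to a fixed-length vector can be
#' substituted (e.g. an adapter around a pretrained embedding) as long as
#' the same extractor is used for both image sets.
#'
#' @param d Output dimension (default 64).
#' @param pool Pooled grid side (default 8).
#' @param channels Expected image channels (default 3).
#' @param seed Seed fixing the projection.
#' @return A function: H x W x C image -> length-d numeric vector.
#' @export
feature_extractor_random <- function(d = 64, pool = 8, channels = 3,
                                     seed = 20) {
  set.seed(seed)
  proj <- matrix(stats::rnorm(pool * pool * channels * d), d,
                 pool * pool * channels) / sqrt(pool * pool * channels)
  function(img) {
    dm <- dim(img)
    stopifnot(length(dm) == 3, dm[3] == channels, all(dm[1:2] >= pool))
    ry <- ceiling(seq_len(dm[1]) * pool / dm[1])
    rx <- ceiling(seq_len(dm[2]) * pool / dm[2])
    pooled <- array(0, c(pool, pool, channels))
    cnt <- array(0, c(pool, pool, channels))
    for (c in seq_len(channels)) {
      s <- rowsum(img[, , c], ry, reorder = TRUE)
      s <- t(rowsum(t(s), rx, reorder = TRUE))
      n <- rowsum(matrix(1, dm[1], dm[2]), ry)
      n <- t(rowsum(t(n), rx))
      pooled[, , c] <- s / n
    }
    as.numeric(proj %*% as.numeric(pooled))
  }
}

features_of <- function(set, extractor) {
  if (is.matrix(set)) return(set)
  t(vapply(set, extractor, numeric(length(extractor(set[[1]])))))
}

#' Frechet distance between two image sets
#'
#' Embeds both sets with the extractor and computes the Frechet distance
#' between Gaussian fits of the features:
#' `||mu_a - mu_b||^2 + Tr(Sa + Sb - 2 (Sa Sb)^{1/2})`. The matrix square
#' root uses the symmetric eigendecomposition of
#' `Sa^{1/2} Sb Sa^{1/2}`, clipping eigenvalues above -1e-6 to zero, so the
#' result is never negative for identical sets. With the identity extractor
#' and feature matrices passed directly this is the closed-form Frechet
#' distance between the empirical Gaussians.
#'
#' @param set_a,set_b Lists of images, or n x d feature matrices (in which
#'   case `extractor` is ignored).
#' @param extractor Feature extractor function (default
#'   [feature_extractor_random()]).
#' @return Non-negative scalar.
#' @export
metric_fid <- function(set_a, set_b, extractor = feature_extractor_random()) {
  fa <- features_of(set_a, extractor)
  fb <- features_of(set_b, extractor)
  if (nrow(fa) < 2 || nrow(fb) < 2) {
    stop("need at least 2 samples per set", call. = FALSE)
  }
  if (nrow(fa) < ncol(fa) || nrow(fb) < ncol(fb)) {
    warning("fewer samples than feature dimensions; covariances are rank-deficient")
  }
  mu_a <- colMeans(fa)
  mu_b <- colMeans(fb)
  sa <- stats::cov(fa)
  sb <- stats::cov(fb)
  ea <- eigen(sa, symmetric = TRUE)
  sqa <- ea$vectors %*% (sqrt(pmax(ea$values, 0)) * t(ea$vectors))
  mid <- sqa %*% sb %*% sqa
  ev <- eigen((mid + t(mid)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-6 * max(abs(ev), 1))) {
    warning("covariance product has significantly negative eigenvalues")
  }
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  max(sum((mu_a - mu_b)^2) + sum(diag(sa)) + sum(diag(sb)) - 2 * tr_sqrt, 0)
}

#' Kernel distance (unbiased MMD^2) between two image sets
#'
#' Polynomial-kernel `k(x, y) = (x'y / d + 1)^3` maximum mean discrepancy,
#' estimated without bias and averaged over `n_subsets` random subsets of
#' `subset_size` items, the standard estimator for kernel distances between
#' image sets. Zero in expectation when both sets come from the same
#' distribution (the estimate itself can be slightly negative).
#'
#' @param set_a,set_b Lists of images or feature matrices.
#' @param extractor Feature extractor (ignored for matrices).
#' @param subset_size Items per subset (>= 2).
#' @param n_subsets Number of subset repetitions.
#' @param seed Seed for subset draws.
#' @return Scalar estimate (can be marginally negative at the null).
#' @export
metric_kid <- function(set_a, set_b,
                       extractor = feature_extractor_random(),
                       subset_size = 50, n_subsets = 10, seed = 1) {
  if (subset_size < 2) stop("subset_size must be >= 2", call. = FALSE)
  fa <- features_of(set_a, extractor)
  fb <- features_of(set_b, extractor)
  d <- ncol(fa)
  kpoly <- function(x, y) (tcrossprod(x, y) / d + 1)^3
  set.seed(seed)
  m <- min(subset_size, nrow(fa), nrow(fb))
  ests <- vapply(seq_len(n_subsets), function(i) {
    ia <- sample.int(nrow(fa), m)
    ib <- sample.int(nrow(fb), m)
    kaa <- kpoly(fa[ia, , drop = FALSE], fa[ia, , drop = FALSE])
    kbb <- kpoly(fb[ib, , drop = FALSE], fb[ib, , drop = FALSE])
    kab <- kpoly(fa[ia, , drop = FALSE], fb[ib, , drop = FALSE])
    (sum(kaa) - sum(diag(kaa))) / (m * (m - 1)) +
      (sum(kbb) - sum(diag(kbb))) / (m * (m - 1)) -
      2 * mean(kab)
  }, numeric(1))
  mean(ests)
}

#' Six-metric evaluation report across methods
#'
#' Evaluates each method's generated images against the common target set
#' with the four paired spatial metrics (L1, RMSE, SSIM, PSNR; averaged over
#' image pairs) and the two distributional metrics (FID, KID; computed on
#' the sets). All methods must be scored against the identical target set,
#' otherwise rows would not be comparable.
#'
#' @param results Named list; each element is a list with `pred` (list of
#'   H x W x 3 images) and `target` (list of same length/shape).
#' @param extractor Feature extractor for FID/KID.
#' @param kid_subset_size,kid_n_subsets,kid_seed KID estimator settings.
#' @return A `metric_report` data.frame with one row per method and columns
#'   `FID`, `KID`, `L1`, `RMSE`, `SSIM`, `PSNR`; direction flags are stored
#'   in `attr(, "direction")` and the best method per column in
#'   `attr(, "best")`.
#' @export
evaluate_methods <- function(results,
                             extractor = feature_extractor_random(),
                             kid_subset_size = 50, kid_n_subsets = 10,
                             kid_seed = 1) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  ref <- results[[1]]$target
  for (r in results) {
    if (length(r$pred) != length(ref)) {
      stop("methods evaluated on different test sets", call. = FALSE)
    }
    if (!isTRUE(all.equal(r$target, ref, tolerance = 1e-12))) {
      stop("methods evaluated against different target sets",
           call. = FALSE)
    }
  }
  ft <- features_of(ref, extractor)
  rows <- lapply(results, function(r) {
    fp <- features_of(r$pred, extractor)
    pair <- function(f) mean(mapply(f, r$pred, r$target))
    psnrs <- mapply(metric_psnr, r$pred, r$target)
    data.frame(
      FID = metric_fid(fp, ft, extractor),
      KID = metric_kid(fp, ft, extractor, subset_size = kid_subset_size,
                       n_subsets = kid_n_subsets, seed = kid_seed),
      L1 = pair(metric_l1),
      RMSE = pair(metric_rmse),
      SSIM = pair(metric_ssim),
      PSNR = mean(psnrs[is.finite(psnrs)]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(results)
  direction <- c(FID = "down", KID = "down", L1 = "down", RMSE = "down",
                 SSIM = "up", PSNR = "up")
  best <- vapply(names(direction), function(m) {
    v <- out[[m]]
    rownames(out)[if (direction[m] == "down") which.min(v) else which.max(v)]
  }, character(1))
  structure(out, direction = direction, best = best,
            class = c("metric_report", "data.frame"))
}

#' @export
print.metric_report <- function(x, ...) {
  dirs <- attr(x, "direction")
  hdr <- paste0(names(dirs), ifelse(dirs == "down", "↓", "↑"))
  y <- as.data.frame(x)
  names(y) <- hdr
  print(signif(as.matrix(y), 4))
  cat("best:", paste(sprintf("%s=%s", names(attr(x, "best")),
                             attr(x, "best")), collapse = " "), "\n")
  invisible(x)
}

#' Export a metric report
#'
#' @param report A [evaluate_methods()] result.
#' @param path Output path (`.csv` or `.json` by extension).
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(metrics = cbind(method = rownames(report),
                           as.data.frame(report)),
           direction = as.list(attr(report, "direction")),
           best = as.list(attr(report, "best"))),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(cbind(method = rownames(report),
                           as.data.frame(report)), path, row.names = FALSE)
  }
  invisible(path)
}
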