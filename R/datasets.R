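#' Tile origins for a regular patch grid
#'
#' Top-left origins of `patch`-sized tiles on a regular grid with the given
#' stride; `stride = patch / 2` reproduces 50% linear overlap between
#' neighbouring tiles, `stride = patch` tiles without overlap.
#'
#' @param size Image side length (pixels).
#' @param patch Tile side length (<= size).
#' @param stride Grid stride (>= 1).
#' @return Integer vector of 1-based origins along one axis.
#' @export
tile_origins <- function(size, patch, stride) {
  if (patch > size) stop("patch must be <= image size", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  seq(1, size - patch + 1, by = stride)
}

extract_tiles <- function(arr, patch, stride) {
  d <- dim(arr)
  oy <- tile_origins(d[1], patch, stride)
  ox <- tile_origins(d[2], patch, stride)
  out <- list()
  for (y in oy) for (x in ox) {
    out[[length(out) + 1]] <- arr[y:(y + patch - 1), x:(x + patch - 1), ,
                                  drop = FALSE]
  }
  out
}

#' Build a paired-patch dataset from phantom tissue images
#'
#' Renders `n_pairs` registered unstained/stained phantom images, assigns
#' them round-robin to `n_groups` synthetic "patients", tiles every image
#' into `patch` x `patch` paired patches on a regular grid with the given
#' stride (default `patch / 2`, i.e. 50% overlap), and splits the patches by
#' patient so no patient contributes to both splits — train/test leakage
#' through overlapping tiles of one section is impossible by construction.
#'
#' @param n_pairs Number of phantom images to render.
#' @param image_size Side length of each rendered image (pixels).
#' @param patch Patch side length.
#' @param stride Tiling stride (default `patch / 2`).
#' @param n_groups Number of synthetic patients.
#' @param test_groups Group indices held out as the test set.
#' @param chromophores Chromophore set for [render_pair()].
#' @param nucleus_density,noise_sd,morph_eps Phantom parameters (see
#'   [generate_layout()] and [render_pair()]).
#' @param seed Master seed; per-image seeds are derived from it.
#' @return A `vs_dataset`: list with `train` and `test` (each a list of
#'   paired patches with fields `unstained` (H x W x N array), `target`
#'   (H x W x 3), `group`, `pair_id`), plus `wavelengths` and `params`.
#' @examples
#' ds <- build_dataset(n_pairs = 2, image_size = 64, patch = 32, seed = 1)
#' length(ds$train)
#' @export
build_dataset <- function(n_pairs, image_size = 128, patch = 64,
                          stride = patch / 2, n_groups = 9,
                          test_groups = c(7, 8, 9),
                          chromophores = default_chromophores(),
                          nucleus_density = 8, noise_sd = 0.01,
                          morph_eps = 0, seed = 1) {
  stopifnot(n_pairs >= 1, n_groups >= 1)
  stride <- as.integer(round(stride))
  test_groups <- unique(as.integer(test_groups))
  if (length(test_groups) >= n_groups || length(test_groups) < 1) {
    stop("test_groups must name a non-empty strict subset of groups",
         call. = FALSE)
  }
  groups <- rep(seq_len(n_groups), length.out = n_pairs)
  train <- list()
  test <- list()
  for (i in seq_len(n_pairs)) {
    lay <- generate_layout(image_size, image_size,
                           nucleus_density = nucleus_density,
                           seed = seed * 10000L + i)
    pair <- render_pair(lay, chromophores, noise_sd = noise_sd,
                        morph_eps = morph_eps, seed = seed * 10000L + i)
    tu <- extract_tiles(unclass(pair$unstained), patch, stride)
    tt <- extract_tiles(pair$stained_rgb, patch, stride)
    for (k in seq_along(tu)) {
      item <- list(unstained = tu[[k]], target = tt[[k]],
                   group = groups[i], pair_id = i)
      if (groups[i] %in% test_groups) {
        test[[length(test) + 1]] <- item
      } else {
        train[[length(train) + 1]] <- item
      }
    }
  }
  structure(list(train = train, test = test,
                 wavelengths = chromophores$wavelengths,
                 params = list(n_pairs = n_pairs, image_size = image_size,
                               patch = patch, stride = stride,
                               n_groups = n_groups,
                               test_groups = test_groups,
                               noise_sd = noise_sd, morph_eps = morph_eps,
                               seed = seed)),
            class = "vs_dataset")
}

#' @export
print.vs_dataset <- function(x, ...) {
  cat(sprintf("<vs_dataset> %d train / %d test patches (%d x %d, %d bands)\n",
              length(x$train), length(x$test), x$params$patch,
              x$params$patch, length(x$wavelengths)))
  invisible(x)
}

#' Prepare model inputs for one reduction method
#'
#' Converts the unstained member of every patch into the representation a
#' model consumes: the full spectral cube (`"full"`, N channels), the CIE
#' 1931 RGB reduction (`"rgb"`, 3 channels), or PCA coefficients (`"pca"`,
#' `n_components` channels, basis fitted on training-split spectra only and
#' frozen for the test split).
#'
#' @param dataset A [build_dataset()] result.
#' @param method `"full"`, `"rgb"` or `"pca"`.
#' @param n_components Components kept for `method = "pca"`.
#' @return The dataset with an `input` array added to every patch (and the
#'   fitted `pca_basis` attached as `$basis` for `method = "pca"`).
#' @export
prepare_inputs <- function(dataset, method = c("pca", "rgb", "full"),
                           n_components = 5) {
  stopifnot(inherits(dataset, "vs_dataset"))
  method <- match.arg(method)
  wl <- dataset$wavelengths
  basis <- NULL
  if (method == "pca") {
    pool <- do.call(rbind, lapply(dataset$train, function(p) {
      d <- dim(p$unstained)
      matrix(p$unstained, d[1] * d[2], d[3])
    }))
    basis <- fit_pca(pool)
  }
  convert <- function(p) {
    d <- dim(p$unstained)
    p$input <- switch(method,
      full = p$unstained,
      # unclipped colorimetric path: gamut clipping is a display concern
      # and would flatten a channel of these near-transparent cubes
      rgb = cube_to_rgb(spectral_cube(p$unstained, wl), clip = FALSE),
      pca = {
        m <- matrix(p$unstained, d[1] * d[2], d[3])
        array(pca_project(m, basis, n_components), c(d[1], d[2],
                                                     n_components))
      })
    p
  }
  dataset$train <- lapply(dataset$train, convert)
  dataset$test <- lapply(dataset$test, convert)
  dataset$method <- method
  dataset$basis <- basis
  dataset
}
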