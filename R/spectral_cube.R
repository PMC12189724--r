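#' Spectral image cube
#'
#' The central data carrier of the package: an H x W x N_lambda array of
#' non-negative transmission (or emission) values with a wavelength axis.
#' Visible-range bright-field acquisition typically yields ~40 wavelength
#' planes over 400-750 nm.
#'
#' @param data Numeric H x W x N array, values >= 0.
#' @param wavelengths Strictly monotone numeric vector of length N (nm).
#' @return A `spectral_cube` (the array with a `wavelengths` attribute).
#' @export
spectral_cube <- function(data, wavelengths) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("data must be an H x W x N array", call. = FALSE)
  }
  if (length(wavelengths) != dim(data)[3]) {
    stop("length(wavelengths) must equal dim(data)[3]", call. = FALSE)
  }
  d <- diff(wavelengths)
  if (length(wavelengths) > 1 && !(all(d > 0) || all(d < 0))) {
    stop("wavelengths must be strictly monotone", call. = FALSE)
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("cube values must be finite and >= 0", call. = FALSE)
  }
  structure(data, wavelengths = as.numeric(wavelengths),
            class = c("spectral_cube", "array"))
}

#' @rdname spectral_cube
#' @param x A `spectral_cube`.
#' @export
cube_wavelengths <- function(x) {
  stopifnot(inherits(x, "spectral_cube"))
  attr(x, "wavelengths")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x)
  wl <- cube_wavelengths(x)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d wavelengths (%g-%g nm)\n",
              d[1], d[2], d[3], min(wl), max(wl)))
  invisible(x)
}

#' Flatten a cube to a pixels-by-wavelengths matrix
#'
#' @param x A `spectral_cube`.
#' @return An (H*W) x N matrix; row order is R's column-major pixel order.
#' @export
cube_to_matrix <- function(x) {
  stopifnot(inherits(x, "spectral_cube"))
  d <- dim(x)
  matrix(as.numeric(x), nrow = d[1] * d[2], ncol = d[3])
}

#' Rebuild a cube from a pixels-by-wavelengths matrix
#'
#' @param m An (H*W) x N matrix.
#' @param height,width Spatial dimensions.
#' @param wavelengths Wavelength axis of length N.
#' @export
matrix_to_cube <- function(m, height, width, wavelengths) {
  stopifnot(nrow(m) == height * width)
  spectral_cube(array(pmax(as.numeric(m), 0), c(height, width, ncol(m))),
                wavelengths)
}

#' Write / read a spectral cube as multi-plane TIFF
#'
#' One 32-bit float plane per wavelength; the wavelength axis is stored as a
#' JSON sidecar (`<path>.meta.json`) holding the wavelength axis and the
#' intensity scale, so a cube round-trips through disk with its metadata.
#'
#' @param x A `spectral_cube`.
#' @param path Output file path.
#' @export
write_cube_tiff <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF i/o", call. = FALSE)
  }
  stopifnot(inherits(x, "spectral_cube"))
  # TIFF sample values live in [0, 1]; divide out the peak and record it
  scale <- max(max(x), 1e-12)
  planes <- lapply(seq_len(dim(x)[3]),
                   function(k) x[, , k, drop = TRUE] / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(wavelengths_nm = cube_wavelengths(x),
                            scale = scale),
                       paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' Write / read an interferogram stack as multi-plane TIFF
#'
#' One float plane per OPD sample; the OPD axis (nm) and intensity scale are
#' stored in a JSON sidecar (`<path>.meta.json`).
#'
#' @param stack H x W x N_opd array of interferogram intensities.
#' @param grid The common [opd_grid()].
#' @param path File path.
#' @export
write_interferogram_tiff <- function(stack, grid, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF i/o", call. = FALSE)
  }
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] == length(grid$opd))
  scale <- max(max(stack), 1e-12)
  planes <- lapply(seq_len(dim(stack)[3]),
                   function(k) stack[, , k, drop = TRUE] / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(opd_nm = grid$opd, scale = scale),
                       paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' @rdname write_interferogram_tiff
#' @export
read_interferogram_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF i/o", call. = FALSE)
  }
  planes <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  opd <- meta$opd_nm
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  stack <- array(0, c(dim(planes[[1]])[1:2], length(planes)))
  for (k in seq_along(planes)) stack[, , k] <- planes[[k]] * scale
  sp <- diff(opd)[1]
  list(stack = stack,
       grid = opd_grid(max(abs(opd)), sp, two_sided = min(opd) < 0))
}

#' @rdname write_cube_tiff
#' @param path Input file path.
#' @export
read_cube_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF i/o", call. = FALSE)
  }
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  metaf <- paste0(path, ".meta.json")
  if (!file.exists(metaf)) stop("missing metadata sidecar: ", metaf,
                                call. = FALSE)
  meta <- jsonlite::fromJSON(metaf)
  wl <- meta$wavelengths_nm
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  arr <- array(0, c(dim(planes[[1]])[1:2], length(planes)))
  for (k in seq_along(planes)) arr[, , k] <- planes[[k]] * scale
  spectral_cube(pmax(arr, 0), wl)
}
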