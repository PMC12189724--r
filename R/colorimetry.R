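#' CIE 1931 colour-matching functions
#'
#' Returns the CIE 1931 2-degree standard-observer colour-matching functions
#' xbar, ybar, zbar evaluated on a wavelength grid. The table is generated from
#' the piecewise-Gaussian analytic fit of Wyman, Sloan and Shirley (multi-lobe
#' sums that approximate the tabulated observer to within ~1%), clamped at zero
#' so all values are non-negative; this keeps the observer embedded in code
#' rather than shipped as an opaque table.
#'
#' @param wavelengths Wavelength grid in nm (default 5 nm steps over
#'   380-780 nm, which covers the 400-750 nm acquisition band).
#' @return A data.frame with columns `wavelength`, `xbar`, `ybar`, `zbar`.
#' @export
cie1931_cmf <- function(wavelengths = seq(380, 780, by = 5)) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  xbar <- 1.056 * g(wavelengths, 599.8, 37.9, 31.0) +
          0.362 * g(wavelengths, 442.0, 16.0, 26.7) -
          0.065 * g(wavelengths, 501.1, 20.4, 26.2)
  ybar <- 0.821 * g(wavelengths, 568.8, 46.9, 40.5) +
          0.286 * g(wavelengths, 530.9, 16.3, 31.1)
  zbar <- 1.217 * g(wavelengths, 437.0, 11.8, 36.0) +
          0.681 * g(wavelengths, 459.0, 26.0, 13.8)
  data.frame(wavelength = wavelengths,
             xbar = pmax(xbar, 0), ybar = pmax(ybar, 0), zbar = pmax(zbar, 0))
}

interp_cmf <- function(cmf, wavelengths) {
  if (max(wavelengths) < min(cmf$wavelength) ||
      min(wavelengths) > max(cmf$wavelength)) {
    stop("spectrum band is disjoint from the colour-matching support",
         call. = FALSE)
  }
  vapply(c("xbar", "ybar", "zbar"), function(col) {
    stats::approx(cmf$wavelength, cmf[[col]], xout = wavelengths,
                  yleft = 0, yright = 0)$y
  }, numeric(length(wavelengths)))
}

#' Tristimulus values of a spectrum
#'
#' Integrates a spectrum against the CIE 1931 colour-matching functions:
#' `X = k * sum(S * xbar * dl)` and likewise for Y, Z, with `k` chosen so that
#' an all-ones spectrum on the same grid maps to Y = 1. Transmission spectra
#' are treated as emissive stimuli under an equal-energy illuminant (no
#' illuminant weighting), so a fully transparent pixel is reference white.
#'
#' @param intensities Spectral values (>= 0), one per wavelength; or a matrix
#'   with one spectrum per row.
#' @param wavelengths Wavelength grid (nm), strictly monotone.
#' @param cmf Colour-matching table from [cie1931_cmf()].
#' @return Numeric XYZ triple, or an n x 3 matrix for matrix input.
#' @examples
#' wl <- seq(400, 750, length.out = 40)
#' spectrum_to_xyz(rep(1, 40), wl)  # equal-energy white, Y = 1
#' @export
spectrum_to_xyz <- function(intensities, wavelengths, cmf = cie1931_cmf()) {
  m <- if (is.matrix(intensities)) intensities else
    matrix(intensities, nrow = 1)
  if (ncol(m) != length(wavelengths)) {
    stop("spectrum length must match wavelength grid", call. = FALSE)
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) < 0)) {
    o <- order(wavelengths)
    wavelengths <- wavelengths[o]
    m <- m[, o, drop = FALSE]
  }
  bars <- interp_cmf(cmf, wavelengths)
  # trapezoidal quadrature weights on a possibly non-uniform grid
  n <- length(wavelengths)
  w <- if (n == 1) 1 else {
    d <- diff(wavelengths)
    c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  }
  k <- 1 / sum(w * bars[, "ybar"])
  xyz <- k * (m %*% (bars * w))
  colnames(xyz) <- c("X", "Y", "Z")
  if (!is.matrix(intensities)) drop(xyz) else xyz
}

# linear sRGB primaries (IEC 61966-2-1), D65 white point
.xyz2rgb_mat <- matrix(c(3.2406, -1.5372, -0.4986,
                         -0.9689, 1.8758, 0.0415,
                         0.0557, -0.2040, 1.0570),
                       nrow = 3, byrow = TRUE)

srgb_gamma <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Convert XYZ tristimulus values to sRGB
#'
#' Applies the standard sRGB primaries matrix followed by the sRGB transfer
#' curve. Out-of-gamut channels are clipped to [0, 1] when `clip = TRUE`
#' (the display default); otherwise they are returned as-is with an attribute
#' `out_of_gamut` flagging affected rows.
#'
#' @param xyz XYZ triple or an n x 3 matrix.
#' @param clip Clip out-of-gamut values to [0, 1]?
#' @return RGB triple or n x 3 matrix.
#' @export
xyz_to_rgb <- function(xyz, clip = TRUE) {
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  if (any(!is.finite(m))) stop("XYZ values must be finite", call. = FALSE)
  lin <- m %*% t(.xyz2rgb_mat)
  oog <- rowSums(lin < -1e-9 | lin > 1 + 1e-9) > 0
  if (clip) lin <- pmin(pmax(lin, 0), 1)
  rgb <- srgb_gamma(pmax(lin, 0))
  if (clip) rgb <- pmin(pmax(rgb, 0), 1)
  colnames(rgb) <- c("R", "G", "B")
  if (!clip) attr(rgb, "out_of_gamut") <- oog
  if (!is.matrix(xyz)) {
    out <- drop(rgb)
    if (!clip) attr(out, "out_of_gamut") <- oog
    out
  } else rgb
}

#' Reduce a spectral cube to an RGB image
#'
#' Per-pixel CIE 1931 reduction of a transmission cube to an H x W x 3 sRGB
#' image in [0, 1] ("rRGB"). Vectorized over pixels; identical to applying
#' [spectrum_to_xyz()] and [xyz_to_rgb()] pixel by pixel.
#'
#' @param cube A [spectral_cube()].
#' @param cmf Colour-matching table.
#' @param clip Clip out-of-gamut values (default TRUE).
#' @return H x W x 3 numeric array in [0, 1].
#' @export
cube_to_rgb <- function(cube, cmf = cie1931_cmf(), clip = TRUE) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube)
  m <- cube_to_matrix(cube)
  xyz <- spectrum_to_xyz(m, cube_wavelengths(cube), cmf)
  rgb <- xyz_to_rgb(xyz, clip = clip)
  array(as.numeric(rgb), c(d[1], d[2], 3))
}

#' Write an RGB image array to PNG
#'
#' @param img H x W x 3 array in [0, 1].
#' @param path Output path.
#' @export
write_rgb_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG output", call. = FALSE)
  }
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
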