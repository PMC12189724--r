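#' Fit a principal-component basis on per-pixel spectra
#'
#' Pools per-pixel spectra (N-vectors, typically N = 40 wavelengths) and
#' computes the mean spectrum, the eigenvectors of the sample covariance
#' matrix `C = t(Xc) %*% Xc / (m - 1)` of the mean-centered data, and the
#' corresponding eigenvalues in descending order. Each eigenvector's sign is
#' fixed so its largest-magnitude element is positive, making the basis
#' reproducible across platforms.
#'
#' @param samples An m x N matrix, one spectrum per row (m >= 2).
#' @return A `pca_basis` object with fields `mean`, `rotation` (N x N
#'   orthonormal columns), `eigenvalues` (length N, descending, >= 0), `n_dim`
#'   and `n_samples`.
#' @examples
#' b <- fit_pca(matrix(rnorm(200), 50, 4))
#' b$eigenvalues
#' @export
fit_pca <- function(samples) {
  if (!is.matrix(samples)) samples <- as.matrix(samples)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  m <- nrow(samples)
  if (m < 2) stop("need at least 2 samples to fit a PCA basis", call. = FALSE)
  mu <- colMeans(samples)
  xc <- sweep(samples, 2, mu)
  cv <- crossprod(xc) / (m - 1)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(mean = mu, rotation = vecs, eigenvalues = vals,
                 n_dim = ncol(samples), n_samples = m),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> N = %d, fitted on %d spectra\n",
              x$n_dim, x$n_samples))
  frac <- x$eigenvalues / sum(x$eigenvalues)
  cat("  variance fractions:",
      paste(sprintf("%.3f", utils::head(frac, 5)), collapse = " "),
      if (x$n_dim > 5) "..." else "", "\n")
  invisible(x)
}

check_basis <- function(basis, n = NULL) {
  if (!inherits(basis, "pca_basis")) {
    stop("expected a 'pca_basis'", call. = FALSE)
  }
  if (!is.null(n) && (n < 0 || n > basis$n_dim)) {
    stop(sprintf("n must lie in [0, %d]", basis$n_dim), call. = FALSE)
  }
  basis
}

#' Project spectra or a cube onto the leading principal components
#'
#' Computes per-pixel coefficients `p_j = <x - mean, v_j>` for the first `n`
#' eigenvectors.
#'
#' @param x An m x N matrix of spectra or a [spectral_cube()].
#' @param basis A [fit_pca()] basis with matching N.
#' @param n Number of components to keep (1..N).
#' @return For matrix input an m x n coefficient matrix; for a cube an
#'   H x W x n array (a "reduced cube") carrying the basis as attribute.
#' @export
pca_project <- function(x, basis, n) {
  check_basis(basis, n)
  if (n < 1) stop("n must be >= 1 for projection", call. = FALSE)
  is_cube <- inherits(x, "spectral_cube")
  m <- if (is_cube) cube_to_matrix(x) else as.matrix(x)
  if (ncol(m) != basis$n_dim) {
    stop("spectral dimension does not match the basis", call. = FALSE)
  }
  p <- sweep(m, 2, basis$mean) %*% basis$rotation[, seq_len(n), drop = FALSE]
  if (is_cube) {
    d <- dim(x)
    structure(array(p, c(d[1], d[2], n)), basis = basis,
              class = c("reduced_cube", "array"))
  } else p
}

#' Reconstruct spectra from principal-component coefficients
#'
#' Inverse of [pca_project()]: `xhat = mean + sum_j p_j v_j`. With `n = N`
#' this is an exact round trip; with `n = 0` (an empty coefficient set) every
#' pixel reconstructs to the mean spectrum.
#'
#' @param p An m x n coefficient matrix or a reduced cube from
#'   [pca_project()].
#' @param basis The [fit_pca()] basis (taken from the reduced cube's
#'   attribute when omitted).
#' @param wavelengths Wavelength axis for cube output (optional).
#' @return An m x N matrix, or a [spectral_cube()] when `p` is a reduced cube
#'   and `wavelengths` is supplied (values clamped at 0), else an H x W x N
#'   array.
#' @export
pca_reconstruct <- function(p, basis = attr(p, "basis"), wavelengths = NULL) {
  check_basis(basis)
  is_cube <- inherits(p, "reduced_cube")
  m <- if (is_cube) {
    d <- dim(p)
    matrix(as.numeric(p), d[1] * d[2], d[3])
  } else as.matrix(p)
  n <- ncol(m)
  check_basis(basis, n)
  xh <- m %*% t(basis$rotation[, seq_len(n), drop = FALSE])
  xh <- sweep(xh, 2, basis$mean, `+`)
  if (is_cube) {
    d <- dim(p)
    if (!is.null(wavelengths)) {
      matrix_to_cube(xh, d[1], d[2], wavelengths)
    } else array(xh, c(d[1], d[2], basis$n_dim))
  } else xh
}

#' Direct reconstruction loss after keeping n components
#'
#' The normalized reconstruction error
#' `sum_i ||x_i - xhat_i^n||^2 / sum_i ||x_i||^2`, computed explicitly by
#' projecting and reconstructing each spectrum. By default both numerator and
#' denominator are evaluated on mean-centered data, which makes the quantity
#' identical to the eigenvalue form ([pca_loss_spectral()]); `centered =
#' FALSE` keeps the raw-x denominator variant.
#'
#' @param samples m x N matrix of spectra.
#' @param basis A [fit_pca()] basis.
#' @param n Components kept (0..N).
#' @param centered Use mean-centered spectra in the denominator (default
#'   TRUE).
#' @return Loss in [0, 1]; 0 for a perfect reconstruction.
#' @export
pca_loss_direct <- function(samples, basis, n, centered = TRUE) {
  check_basis(basis, n)
  samples <- as.matrix(samples)
  xc <- sweep(samples, 2, basis$mean)
  ref <- if (centered) xc else samples
  denom <- sum(ref^2)
  if (denom == 0) stop("all-zero samples: loss undefined", call. = FALSE)
  if (n == 0) return(sum(xc^2) / denom)
  v <- basis$rotation[, seq_len(n), drop = FALSE]
  resid <- xc - (xc %*% v) %*% t(v)
  sum(resid^2) / denom
}

#' Eigenvalue (spectral) form of the reconstruction loss
#'
#' `Loss_n = 1 - sum(lambda_1..n) / sum(lambda_1..N)`: the variance fraction
#' not captured by the first n components. Agrees with [pca_loss_direct()] on
#' the training data when that is evaluated on centered spectra.
#'
#' @param basis A [fit_pca()] basis.
#' @param n Components kept (0..N).
#' @return Loss in [0, 1].
#' @export
pca_loss_spectral <- function(basis, n) {
  check_basis(basis, n)
  tot <- sum(basis$eigenvalues)
  if (tot <= 0) stop("zero total variance: loss undefined", call. = FALSE)
  1 - sum(basis$eigenvalues[seq_len(n)]) / tot
}

#' Information curve over the number of components
#'
#' The retained-information curve `(n, 1 - Loss_n)` for n = 1..N: the
#' cumulative variance fraction captured by the leading components. It is
#' non-decreasing and reaches 1 at n = N.
#'
#' @param basis A [fit_pca()] basis.
#' @return A data.frame with columns `n` and `information`.
#' @export
information_curve <- function(basis) {
  check_basis(basis)
  tot <- sum(basis$eigenvalues)
  if (tot <= 0) stop("zero total variance", call. = FALSE)
  data.frame(n = seq_len(basis$n_dim),
             information = cumsum(basis$eigenvalues) / tot)
}

#' Serialize / load a PCA basis as JSON
#'
#' Plain-text JSON serialization (mean, rotation, eigenvalues) so a basis
#' fitted on a training split can be frozen and reused.
#'
#' @param basis A [fit_pca()] basis.
#' @param path File path.
#' @export
write_pca_basis <- function(basis, path) {
  check_basis(basis)
  jsonlite::write_json(
    list(mean = basis$mean, rotation = basis$rotation,
         eigenvalues = basis$eigenvalues, n_dim = basis$n_dim,
         n_samples = basis$n_samples),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_pca_basis
#' @export
read_pca_basis <- function(path) {
  o <- jsonlite::fromJSON(path)
  structure(list(mean = as.numeric(o$mean),
                 rotation = matrix(as.numeric(o$rotation), o$n_dim, o$n_dim),
                 eigenvalues = as.numeric(o$eigenvalues),
                 n_dim = as.integer(o$n_dim),
                 n_samples = as.integer(o$n_samples)),
            class = "pca_basis")
}
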