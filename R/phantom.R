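#' Synthetic tissue layout
#'
#' Draws a reproducible random tissue geometry: elliptical nuclei scattered
#' over a stromal background with a few larger lumen (empty) regions, the
#' structural vocabulary of a breast-biopsy section. The per-pixel class map
#' uses labels 0 = lumen/background, 1 = cytoplasm/stroma, 2 = nucleus.
#'
#' @param height,width Image size in pixels.
#' @param nucleus_density Expected nuclei per 100 x 100 pixel area.
#' @param lumen_density Expected lumen blobs per 100 x 100 pixel area.
#' @param seed Integer seed; the layout is a pure function of the arguments.
#' @return A `tissue_layout` with fields `class_map` (H x W integer matrix),
#'   `nuclei` (data.frame of ellipse parameters), `height`, `width`, `seed`.
#' @examples
#' lay <- generate_layout(128, 128, nucleus_density = 8, seed = 1)
#' table(lay$class_map)
#' @export
generate_layout <- function(height, width, nucleus_density = 8,
                            lumen_density = 0.8, seed = 1) {
  if (height < 1 || width < 1) {
    stop("layout dimensions must be positive", call. = FALSE)
  }
  if (nucleus_density < 0 || lumen_density < 0) {
    stop("densities must be >= 0", call. = FALSE)
  }
  rs <- local_rng(seed)
  area <- height * width / 1e4
  cls <- matrix(1L, height, width)

  # lumen: large soft ellipses cut out of the stroma
  n_lum <- rs$rpois(lumen_density * area)
  lumen <- draw_ellipses(rs, n_lum, height, width,
                         ax_range = c(8, 22), ecc_range = c(0.5, 1))
  for (e in lumen) cls[e] <- 0L

  # nuclei: small dense ellipses, drawn last so they sit on top
  n_nuc <- rs$rpois(nucleus_density * area)
  nuc_list <- draw_ellipses(rs, n_nuc, height, width,
                            ax_range = c(2.5, 6), ecc_range = c(0.55, 1),
                            params = TRUE)
  for (e in nuc_list$masks) cls[e] <- 2L

  structure(list(class_map = cls, nuclei = nuc_list$params,
                 height = height, width = width, seed = seed),
            class = "tissue_layout")
}

# small deterministic RNG scope: functions drawing from a private stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
    s
  }
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
    out
  }
  list(
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    rpois = function(lambda) draw(stats::rpois, 1, lambda)
  )
}

draw_ellipses <- function(rs, n, height, width, ax_range, ecc_range,
                          params = FALSE) {
  masks <- list()
  rows <- matrix(0, 0, 5)
  if (n > 0) {
    cy <- rs$runif(n, 1, height)
    cx <- rs$runif(n, 1, width)
    a <- rs$runif(n, ax_range[1], ax_range[2])
    b <- a * rs$runif(n, ecc_range[1], ecc_range[2])
    th <- rs$runif(n, 0, pi)
    yy <- matrix(seq_len(height), height, width)
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    for (i in seq_len(n)) {
      dy <- yy - cy[i]
      dx <- xx - cx[i]
      u <- dy * cos(th[i]) + dx * sin(th[i])
      v <- -dy * sin(th[i]) + dx * cos(th[i])
      masks[[i]] <- which((u / a[i])^2 + (v / b[i])^2 <= 1)
    }
    rows <- cbind(cy, cx, a, b, th)
  }
  if (params) {
    list(masks = masks,
         params = stats::setNames(as.data.frame(rows),
                                  c("center_y", "center_x", "axis_a",
                                    "axis_b", "angle")))
  } else masks
}

#' Default chromophore set for the tissue phantom
#'
#' Absorbance spectra (dimensionless optical density per unit concentration)
#' for each tissue class in the unstained and stained states, as smooth
#' Gaussian bands on the working wavelength grid. These are synthetic
#' stand-ins chosen to reproduce the qualitative behaviour of real sections:
#' unstained tissue is nearly transparent with weak, class-distinct bands;
#' after H&E staining nuclei carry a strong hematoxylin-like band (centred
#' ~590 nm, so nuclei look blue-violet) and stroma an eosin-like band
#' (~525 nm, so stroma looks pink). They are not measured endmember spectra.
#'
#' @param wavelengths Wavelength grid in nm.
#' @return A `chromophore_set`: list with `wavelengths` and an `absorbance`
#'   list keyed by `unstained`/`stained`, each a 3 x N matrix (rows = classes
#'   lumen, stroma, nucleus).
#' @export
default_chromophores <- function(wavelengths = seq(400, 750,
                                                   length.out = 40)) {
  band <- function(center, width, amp) amp * exp(-((wavelengths - center) /
                                                     width)^2)
  unst <- rbind(
    lumen   = band(500, 200, 0.004),
    stroma  = band(560, 90, 0.05) + band(430, 60, 0.02),
    nucleus = band(480, 80, 0.09) + band(600, 90, 0.03)
  )
  stained <- rbind(
    lumen   = band(500, 200, 0.01),
    stroma  = band(525, 45, 0.55) + band(430, 50, 0.08),   # eosin-like
    nucleus = band(590, 65, 1.05) + band(525, 45, 0.25)    # hematoxylin-like
  )
  structure(list(wavelengths = wavelengths,
                 absorbance = list(unstained = unst, stained = stained)),
            class = "chromophore_set")
}

#' Render a registered unstained/stained phantom pair
#'
#' Renders the Beer-Lambert transmission of a [generate_layout()] geometry in
#' both stain states: `T(x, lambda) = 10^(-sum_c conc_c(x) eps_c(lambda))`,
#' plus additive Gaussian detector noise, clipped to [0, 1.2]. Per-pixel
#' concentrations follow the class map modulated by a smooth random texture
#' so images carry within-class structure. The stained RGB target is the CIE
#' 1931 reduction of the stained cube. With `morph_eps > 0` the lumen regions
#' of the stained member are randomly dilated or eroded by up to `morph_eps`
#' pixels, emulating the small staining-induced morphology changes seen
#' between scans of the same section; `morph_eps = 0` gives perfect pixelwise
#' registration.
#'
#' @param layout A [generate_layout()] result.
#' @param chromophores A [default_chromophores()]-style set.
#' @param noise_sd Additive Gaussian noise sd on transmission (default 0.01).
#' @param morph_eps Maximum boundary shift (pixels) applied to the stained
#'   member's lumen regions (default 0).
#' @param seed Integer seed for noise, texture and morphology.
#' @return A `phantom_pair`: list with `unstained` ([spectral_cube()]),
#'   `stained_cube`, `stained_rgb` (H x W x 3 in [0, 1]), `layout`,
#'   `stained_class_map`, and `meta`.
#' @export
render_pair <- function(layout, chromophores = default_chromophores(),
                        noise_sd = 0.01, morph_eps = 0, seed = 1) {
  stopifnot(inherits(layout, "tissue_layout"))
  if (noise_sd < 0 || morph_eps < 0) {
    stop("noise_sd and morph_eps must be >= 0", call. = FALSE)
  }
  wl <- chromophores$wavelengths
  h <- layout$height
  w <- layout$width
  rs <- local_rng(seed + 7919)

  # smooth multiplicative texture shared by both members (same tissue)
  texture <- blur_matrix(matrix(rs$rnorm(h * w), h, w), sigma = 3)
  texture <- pmax(1 + 0.18 * texture / max(stats::sd(texture), 1e-12), 0.2)

  cls_un <- layout$class_map
  cls_st <- if (morph_eps > 0) {
    perturb_lumen(cls_un, morph_eps, rs)
  } else cls_un

  mk_cube <- function(cls, eps_mat) {
    conc <- matrix(0, h * w, 3)
    for (k in 0:2) conc[, k + 1] <- as.numeric(cls == k) * texture
    od <- conc %*% eps_mat                 # (H*W) x N optical density
    tr <- 10^(-od)
    if (noise_sd > 0) {
      tr <- tr + matrix(rs$rnorm(length(tr), sd = noise_sd), nrow(tr))
    }
    tr <- pmin(pmax(tr, 0), 1.2)
    matrix_to_cube(tr, h, w, wl)
  }

  unstained <- mk_cube(cls_un, chromophores$absorbance$unstained)
  stained_cube <- mk_cube(cls_st, chromophores$absorbance$stained)
  stained_rgb <- cube_to_rgb(stained_cube)

  structure(list(unstained = unstained, stained_cube = stained_cube,
                 stained_rgb = stained_rgb, layout = layout,
                 stained_class_map = cls_st,
                 meta = list(seed = seed, noise_sd = noise_sd,
                             morph_eps = morph_eps)),
            class = "phantom_pair")
}

# separable Gaussian blur of a matrix with reflect padding
blur_matrix <- function(m, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(x) {
    n <- length(x)
    xp <- c(x[r:1], x, x[n:(n - r + 1)])
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + n)]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

# randomly dilate (positive) or erode (negative) the lumen class by up to
# eps pixels, leaving the unstained member untouched
perturb_lumen <- function(cls, eps, rs) {
  shift <- round(rs$runif(1, -eps, eps))
  lum <- cls == 0L
  if (!any(lum) || shift == 0) return(cls)
  m <- lum
  for (i in seq_len(abs(shift))) {
    m <- if (shift > 0) dilate4(m) else !dilate4(!m)
  }
  out <- cls
  out[m & cls == 1L] <- 0L   # grown lumen displaces stroma, never nuclei
  out[lum & !m] <- 1L        # eroded lumen closes up as stroma
  out
}

# 4-neighbour binary dilation
dilate4 <- function(m) {
  nb <- m
  nb[-1, ] <- nb[-1, ] | m[-nrow(m), ]
  nb[-nrow(m), ] <- nb[-nrow(m), ] | m[-1, ]
  nb[, -1] <- nb[, -1] | m[, -ncol(m)]
  nb[, -ncol(m)] <- nb[, -ncol(m)] | m[, -1]
  nb
}
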