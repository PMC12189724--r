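test_that("simulated interferograms follow the raised-cosine forward model", {
  grid <- opd_grid(10000, 100)
  # monochromatic line: pure raised cosine at spatial frequency 1/lambda
  ig <- simulate_interferogram(1, 550, grid)
  expect_equal(ig$intensity, (1 + cos(2 * pi * grid$opd / 550)) / 2)
  # zero OPD carries the total spectral power
  sp <- smooth_spectrum()
  ig2 <- simulate_interferogram(sp, wl40, grid)
  expect_equal(ig2$intensity[1], sum(sp))
  # zero spectrum gives a zero interferogram
  expect_equal(simulate_interferogram(rep(0, 40), wl40, grid)$intensity,
               rep(0, length(grid$opd)))
  # two-line beat: envelope node at delta = 1 / (2 dnu)
  l1 <- 500; l2 <- 520
  igb <- simulate_interferogram(c(1, 1), c(l1, l2), grid)
  dnu <- 1 / l1 - 1 / l2
  ac <- igb$intensity - 1
  node <- 1 / (2 * dnu)
  near_node <- abs(grid$opd - node) < 250
  far <- abs(grid$opd) < 2000
  expect_lt(max(abs(ac[near_node])), 0.25 * max(abs(ac[far])))
  expect_error(simulate_interferogram(numeric(0), numeric(0), grid),
               "non-empty")
})

test_that("apodization windows behave as defined", {
  grid <- opd_grid(5000, 100)
  ig <- simulate_interferogram(smooth_spectrum(), wl40, grid)
  expect_identical(apodize(ig, "none"), ig)
  h <- apodize(ig, "hann")
  n <- length(h$intensity)
  expect_equal(h$intensity[n], 0)          # endpoint scaled to zero
  expect_equal(h$intensity[1], ig$intensity[1])  # zero-OPD untouched
  expect_error(apodize(ig, "bogus"), "unknown")
  # hann suppresses reconstruction sidelobes of a monochromatic line
  dg <- opd_grid(40000, 100, two_sided = TRUE)
  line <- simulate_interferogram(1, 550, dg)
  out_wl <- seq(420, 700, by = 2)
  side <- function(w) {
    r <- reconstruct_spectrum(line, out_wl, window = w)
    max(r$intensities[abs(r$wavelengths - 550) > 30])
  }
  expect_lt(side("hann"), side("none"))
})

test_that("zero filling extends the grid without changing content", {
  grid <- opd_grid(5000, 100)
  ig <- simulate_interferogram(smooth_spectrum(), wl40, grid)
  expect_identical(zero_fill(ig, 1), ig)
  z2 <- zero_fill(ig, 2)
  n <- length(ig$intensity)
  expect_length(z2$intensity, 2 * n)
  expect_equal(z2$intensity[(n + 1):(2 * n)], rep(0, n))
  expect_equal(z2$grid$spacing, grid$spacing)
  expect_error(zero_fill(ig, 0), "factor")
  # peak position of a line is stable under zero filling
  dg <- opd_grid(40000, 100, two_sided = TRUE)
  line <- simulate_interferogram(1, 550, dg)
  out_wl <- seq(500, 600, by = 1)
  pk <- vapply(c(1, 2, 4), function(zf) {
    r <- reconstruct_spectrum(line, out_wl, zero_fill_factor = zf)
    r$wavelengths[which.max(r$intensities)]
  }, numeric(1))
  expect_lt(max(pk) - min(pk), 8)  # within one original-resolution bin
})

test_that("round trip on smooth spectra meets the window error budgets", {
  sp <- smooth_spectrum()
  # default pipeline: hann + magnitude + zero-fill 2, dense two-sided grid
  grid <- opd_grid(40000, 90, two_sided = TRUE)
  ig <- simulate_interferogram(sp, wl40, grid)
  rec <- reconstruct_spectrum(ig, wl40)$intensities
  expect_lt(sqrt(sum((rec - sp)^2) / sum(sp^2)), 0.05)
  expect_true(all(rec >= 0))
  # phase-corrected path at depth: < 5% with hann, < 1% without apodization
  deep <- opd_grid(160000, 90, two_sided = TRUE)
  igd <- simulate_interferogram(sp, wl40, deep)
  for (spec in list(list(w = "hann", tol = 0.05),
                    list(w = "none", tol = 0.01))) {
    r <- reconstruct_spectrum(igd, wl40, window = spec$w,
                              phase_method = "mertz")$intensities
    expect_lt(sqrt(sum((r - sp)^2) / sum(sp^2)), spec$tol)
  }
  # interferogram of zeros reconstructs to a zero spectrum
  z <- reconstruct_spectrum(interferogram(grid,
                                          rep(0, length(grid$opd))), wl40)
  expect_equal(z$intensities, rep(0, 40))
})

test_that("monochromatic reconstruction peaks at the source wavelength", {
  grid <- opd_grid(40000, 100, two_sided = TRUE)
  ig <- simulate_interferogram(1, 550, grid)
  r <- reconstruct_spectrum(ig, seq(420, 700, by = 2))
  expect_lt(abs(r$wavelengths[which.max(r$intensities)] - 550), 5)
})

test_that("the real-part reconstruction path is linear", {
  grid <- opd_grid(40000, 100, two_sided = TRUE)
  s1 <- smooth_spectrum()
  s2 <- rev(s1)
  i1 <- simulate_interferogram(s1, wl40, grid)
  i2 <- simulate_interferogram(s2, wl40, grid)
  mix <- interferogram(grid, 2 * i1$intensity + 0.5 * i2$intensity)
  rec <- function(ig) {
    reconstruct_spectrum(ig, wl40, phase_method = "real",
                         clamp_negative = FALSE)$intensities
  }
  lhs <- rec(mix)
  rhs <- 2 * rec(i1) + 0.5 * rec(i2)
  expect_lt(sqrt(sum((lhs - rhs)^2) / sum(rhs^2)), 1e-6)
})

test_that("line width in wavelength grows ~quadratically with wavelength", {
  grid <- opd_grid(60000, 90, two_sided = TRUE)
  fwhm <- vapply(c(450, 700), function(lam) {
    ig <- simulate_interferogram(1, lam, grid)
    out <- seq(lam - 50, lam + 50, by = 0.1)
    r <- reconstruct_spectrum(ig, out, window = "hann",
                              phase_method = "mertz")
    above <- r$wavelengths[r$intensities > max(r$intensities) / 2]
    max(above) - min(above)
  }, numeric(1))
  ratio <- fwhm[2] / fwhm[1]
  expect_gt(ratio, 0.75 * (700 / 450)^2)
  expect_lt(ratio, 1.25 * (700 / 450)^2)
})

test_that("band limits are enforced and out-of-band queries clamped", {
  grid <- opd_grid(20000, 100)
  ig <- simulate_interferogram(smooth_spectrum(), wl40, grid)
  expect_error(reconstruct_spectrum(ig, c(150, 500)), "Nyquist")
  expect_warning(reconstruct_spectrum(ig, c(500, 600, 5e5)), "clamped")
  expect_error(opd_grid(100, -5), "spacing")
  expect_error(interferogram(grid, c(1, 2)), "length")
})

test_that("cube reconstruction recovers per-pixel spectra", {
  grid <- opd_grid(30000, 100, two_sided = TRUE)
  wl <- seq(420, 720, length.out = 12)
  s1 <- 0.5 + 0.4 * exp(-((wl - 520) / 60)^2)
  s2 <- 0.8 - 0.4 * exp(-((wl - 620) / 70)^2)
  stack <- array(0, c(2, 1, length(grid$opd)))
  stack[1, 1, ] <- simulate_interferogram(s1, wl, grid)$intensity
  stack[2, 1, ] <- simulate_interferogram(s2, wl, grid)$intensity
  cube <- reconstruct_cube(stack, grid, wl)
  expect_s3_class(cube, "spectral_cube")
  expect_lt(sqrt(sum((cube[1, 1, ] - s1)^2) / sum(s1^2)), 0.08)
  expect_lt(sqrt(sum((cube[2, 1, ] - s2)^2) / sum(s2^2)), 0.08)
})
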