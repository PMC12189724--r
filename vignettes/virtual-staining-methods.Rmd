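---
title: "Virtual H&E staining from spectral images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual H&E staining from spectral images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrastain)
```

## The problem

Histopathological diagnosis rests on stained tissue sections, most often
Hematoxylin and Eosin (H&E): hematoxylin renders nuclei blue-violet, eosin
renders cytoplasm and stroma pink. Staining is slow, destructive and
operator-dependent. An alternative is to image the *unstained* section with a
modality that captures more than three colour channels and to synthesize the
H&E appearance computationally. This package implements such a pipeline for
visible-range spectral imaging: every pixel carries a transmission spectrum
(about 40 samples over 400--750 nm) rather than an RGB triple, and a
conditional GAN learns the mapping from the unstained spectral representation
to the stained RGB appearance.

The package covers the full chain as testable code: the acquisition-geometry
arithmetic of the imaging system, a Fourier-transform spectroscopy simulator
(the spectral separation mechanism of the instrument), a synthetic tissue
phantom standing in for biopsy data, CIE 1931 colorimetric reduction,
per-pixel PCA reduction with its information curve, the Pix2Pix-style
generator/discriminator pair with its losses and schedule, and the six
evaluation metrics (L1, RMSE, PSNR, SSIM, FID, KID).

## Acquisition geometry

`optical_config()` captures the imaging parameters: a 20x objective of NA
0.8 in front of a camera with 5.5 um pixels exposed for 10 us. Three
closed-form quantities document the regime:

```{r geometry}
cfg <- optical_config()
geometry_report(cfg, n_pixels = 256)
```

Each camera pixel images 275 nm of sample, so a 256-pixel patch spans about
70 um. The Rayleigh limit `0.61 * lambda / NA` is ~610 nm; the reference
wavelength defaults to 800 nm (the red edge of the sensitivity band), the
choice under which the quoted resolution is the worst case over the band —
the wavelength entering this figure is an assumption documented here, not a
measured property. Because 275 nm < 610 nm the system oversamples the optics,
and during continuous scanning the stage speed must keep the motion smear
below a quarter pixel per exposure.

## Fourier spectral reconstruction

The instrument measures, at every pixel, intensity as a function of optical
path difference (OPD) — an interferogram — and recovers the spectrum by
Fourier transform. The simulator uses the standard raised-cosine forward
model $I(\delta) = \sum_k S_k\,(1 + \cos 2\pi \nu_k \delta)/2$ with
$\nu_k = 1/\lambda_k$. Reconstruction follows the canonical pipeline:
DC removal, apodization (`none`, `triangular`, `hann`, `cosine`),
zero-filling, FFT, phase correction, amplitude calibration, and resampling
onto the requested wavelength grid.

Numerical choices worth stating explicitly:

* **Resampling is integral-conserving.** The transform estimates a spectral
  *density* per unit wavenumber (the instrument line shape integrates to
  `1/spacing` whatever the window), and the density is integrated over each
  output wavenumber cell rather than point-sampled. A discrete line then
  deposits its full power into the cell containing it, so spectra simulated
  from grid samples round-trip even when the instrument resolution is much
  finer than the grid. Point sampling (plain interpolation) would make the
  result oscillate with the ratio of line spacing to resolution.
* **Grid sidedness matters.** A symmetric two-sided OPD grid with a full
  apodization window has a compact, fast-decaying line shape; a one-sided
  grid behaves like an even extension with a kink and leaks tens of percent
  of each line's power into broad tails. Quantitative round trips in the
  tests therefore use `opd_grid(..., two_sided = TRUE)`.
* **Phase correction.** `magnitude` (the default) is simplest and always
  non-negative but collects quadrature leakage into a positive baseline;
  `mertz` estimates a low-resolution phase from a short symmetric segment
  around zero OPD and keeps the real part; `real` is provided for the
  noiseless symmetric forward model and is exactly linear. On a dense
  two-sided grid the round-trip error of a smooth 40-point spectrum is
  2-3% with the default settings (hann, zero-fill 2, magnitude), under
  0.1% with hann+mertz at larger OPD depth, and under 1% without
  apodization — apodization trades resolution for sidelobe suppression, and
  the tests quantify both sides of that trade.
* Fourier resolution is constant in wavenumber, so in wavelength it grows
  roughly as $\lambda^2$ at fixed maximum OPD (about 5 nm at 400 nm versus
  20 nm at 800 nm for the depths used here); a property test asserts the
  quadratic growth of the reconstructed line width.

## The tissue phantom

Real paired scans of the same section before and after staining are not
distributable with the package, so a synthetic phantom generates registered
pairs with the structural vocabulary of a biopsy section: elliptical nuclei
(a Poisson number, default 8 per 100x100 px), a stromal background, and
larger lumen blobs. Rendering is Beer--Lambert:
$T(x,\lambda) = 10^{-\sum_c \mathrm{conc}_c(x)\,\varepsilon_c(\lambda)}$,
plus additive Gaussian detector noise (sd 0.01 by default, a visually
plausible transmission noise level) clipped to [0, 1.2].

The chromophore spectra are smooth synthetic Gaussians, not measured
endmembers: unstained classes carry weak, class-distinct bands (tissue is
nearly transparent before staining), while the stained state has a strong
nuclear band centred near 590 nm (hematoxylin-like, nuclei render
blue-violet) and a stromal band near 525 nm (eosin-like, stroma renders
pink). A smooth multiplicative texture field shared by both members provides
within-class structure. `morph_eps` optionally dilates or erodes lumen
boundaries on the stained member only, emulating the small
staining-induced morphology changes observed between scans of the same
section; its default is 0 so pairs are perfectly registered unless asked
otherwise.

What the phantom does *not* emulate: optical scattering, autofluorescence,
defocus, stitching artifacts, inter-patient variability beyond random
geometry, or realistic chromophore spectra. Passing tests on the phantom
therefore demonstrate that the pipeline is implemented correctly and can
learn a solvable spectral-to-stain mapping; they do not certify performance
on real tissue.

A "patient" is a top-level seed group: `build_dataset()` assigns whole
phantom sections to groups and splits train/test by group, mirroring
patient-wise splitting. Tiles of one section can never appear in both
splits, which matters because tiles at 50% overlap (the default stride is
half the patch) share pixels.

## Dimensionality reduction

Two reductions of the unstained cube are compared against the full spectrum:

* **rRGB** — CIE 1931 reduction: tristimulus integration against the 2°
  standard-observer colour-matching functions (embedded analytically via the
  Wyman--Sloan--Shirley piecewise-Gaussian fit, clamped at zero), then the
  sRGB primaries matrix and transfer curve. Transmission spectra are treated
  as emissive stimuli under an equal-energy illuminant — no illuminant
  multiplication — since the stained targets are rendered and consumed under
  the same convention; the normalization makes an all-ones spectrum map to
  Y = 1 (reference white).
* **PCA** — per-pixel principal components of the unstained spectra. The
  basis is fitted on the *training split only* and frozen, preventing
  leakage. Per-pixel fitting (spectral dimension N = 40) rather than
  whole-image flattening is the only reading under which a 3--15 component
  sweep and per-component variance fractions are meaningful.

The reconstruction loss after keeping $n$ components is available in two
forms: the direct form $\sum_i \|x_i - \hat x_i^n\|^2 / \sum_i \|x_i\|^2$
computed by explicit reconstruction, and the eigenvalue form
$1 - \sum_{j \le n}\lambda_j / \sum_j \lambda_j$. Both numerator and
denominator of the direct form are evaluated on mean-centred spectra by
default, which makes the two forms identical (the test suite checks
agreement to 1e-6 on random matrices); the raw-denominator variant is kept
as a documented option (`centered = FALSE`). Eigenvector signs are fixed
deterministically (largest-magnitude element positive). `information_curve()`
returns $(n, 1-\mathrm{Loss}_n)$, the cumulative variance fraction:

```{r pca}
lay <- generate_layout(128, 128, nucleus_density = 8, seed = 1)
pair <- render_pair(lay, seed = 1)
basis <- fit_pca(cube_to_matrix(pair$unstained))
head(information_curve(basis), 6)
```

On phantom spectra the first component dominates (over half of the variance)
and five components retain roughly three quarters of it, after which the
curve flattens into the isotropic noise floor — PCA truncation therefore
also acts as noise cleaning, and a property test checks that isotropic noise
of variance $\sigma^2$ lifts every eigenvalue by about $\sigma^2$.

## The conditional GAN

The generator is a U-Net: 3x3 convolutions throughout, batch normalization
and LeakyReLU (slope 0.1) after every convolution, stride-2 convolutions
down, nearest-neighbour upsampling and skip concatenation up, and a linear
3-channel output head operating in normalized target space. The
discriminator is a patch classifier over the concatenated (input
representation, candidate image): three stride-2 blocks (no normalization on
the first, the usual convention) and a 1-channel logit head, so each output
cell rates a local patch rather than the whole image.

The generator loss is

$$\mathcal{L}_G = -\log D(G(x), x) \; + \; \gamma_1\,\|\tilde G(x) - \tilde y\|_1
\; + \; \gamma_2\,\mathrm{TV}(G(x)),$$

with $\gamma_1 = 500$, $\gamma_2 = 10^{-4}$, where the tilde denotes a 5x5
Gaussian blur (sigma 1.0; only the kernel size is prescribed, the sigma is
this package's choice) applied to both images so the similarity term rewards
structure rather than pixel noise, and TV is the anisotropic *squared*
total variation. Design decisions on points the loss formulas leave open:

* The adversarial term uses the standard non-saturating form
  $-\log D(G(x))$; the discriminator minimizes the patch-averaged
  cross-entropy $-\tfrac12[\log D(x,y) + \log(1 - D(x,G(x)))]$. A
  literal half-difference of log-probabilities is not a bounded objective,
  so the conventional cGAN form is implemented and exposed in
  `discriminator_loss()`.
* The L1 term uses *mean* reduction over pixels and channels, so
  $\gamma_1 = 500$ is scale-stable across patch sizes.
* The discriminator is conditioned by channel concatenation of input and
  candidate, the Pix2Pix convention.

Training uses Adam (beta 0.9/0.999) for both networks with the staircase
schedule: learning rate 0.02 multiplied by 0.85 every five epochs
(`lr_at_epoch(train_config(), 10)` is 0.01445). Inputs and targets are
normalized channelwise to the training-split mean and standard deviation.
Batch-norm layers use the statistics of the presented batch at inference as
well (single image, i.e. instance statistics), the usual convention for
batch-normalized image-translation generators. A non-finite loss raises a
`vs_divergence_error` carrying the last finite checkpoint.

The convolution, batch-norm and resampling kernels are implemented in
C++ (im2col + GEMM) with single-precision arithmetic inside the GEMM — the
optimizer noise floor of GAN training sits far above float rounding — and
every operator's adjoint is verified against finite differences in the test
suite.

## Evaluation

Four paired metrics are computed per image pair and averaged: L1, RMSE,
PSNR (peak 1.0), and SSIM (11x11 Gaussian window, sigma 1.5,
$C_1 = 0.01^2$, $C_2 = 0.03^2$, per channel then averaged). Two
distributional metrics compare image *sets*: FID (Frechet distance between
Gaussian fits of features; matrix square root via symmetric
eigendecomposition with negative-eigenvalue clipping) and KID (unbiased
MMD^2 with the polynomial kernel $(x^\top y/d + 1)^3$, averaged over random
subsets, seed-deterministic).

The feature extractor behind FID/KID is pluggable. The default is a
deterministic random-projection embedding (8x8 average pooling, fixed
Gaussian projection to 64 dimensions): fully self-contained, seeded, and
sensitive to colour and coarse spatial statistics at this image scale.
Published FID/KID magnitudes depend on a specific pretrained network and
are not comparable across extractors, so only orderings and
identity/null behaviour are meaningful here; a test demonstrates the two
metric families are non-redundant (spatially shifted predictions score well
distributionally and poorly paired; faded predictions the reverse).

## The desk-scale experiment

`vs_experiment()` is the end-to-end comparison: 50 phantom sections of
128x128 px tiled into 200 registered 64x64 patches over nine synthetic
patients (three held out), one model per representation (PCA-n, rRGB, full
spectrum), 20 epochs with the default schedule, then the six-metric report
on the common held-out targets. These problem sizes are the package's
standard desk-scale study: large enough that all three representations
train to a meaningful mapping (the held-out blurred-L1 typically falls by
well over half from its first epoch), small enough to run on a single CPU
core. The `tiny` generator preset (depth 3, base width 16) is sized to the
same scale. The full-scale preset (depth 4, width 64) and 100-epoch
schedule remain the defaults of their respective configuration objects.

## Known limitations

* The phantom's chromophores are invented; absolute metric values on
  phantom data say nothing about absolute performance on tissue.
* FID/KID magnitudes are extractor-specific by construction.
* The GAN trains in single precision on one core; bitwise reproducibility
  is platform-level (same BLAS), not IEEE-exact across libraries.
* Registration of real pairs (the manual step in practice) is out of
  scope: phantom pairs are registered by construction, optionally degraded
  by `morph_eps`.
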