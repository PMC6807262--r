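---
title: "seedspec: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedspec: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Seed lots of closely related crop varieties are visually indistinguishable,
but their near-infrared reflectance spectra differ subtly through
composition (protein, oil, moisture). A line-scan NIR hyperspectral camera
images a tray of seeds and records a full spectrum (here ~256 bands,
roughly 874–1734 nm) at every pixel. `seedspec` implements a complete
pipeline from the raw instrument cube to per-seed variety calls:

1. **Reflectance calibration.** The raw intensity cube is converted to
   reflectance with white/dark reference images,
   `R = (I_raw - I_dark) / (I_white - I_dark)` element-wise. References may
   be full frames or a single reference line broadcast along the scan axis
   — line-scan systems commonly record one line; both are supported and
   equivalent when the illumination is stable along the scan. Reflectance
   is *not* clipped to [0, 1]: clipping would silently distort spectra, so
   out-of-range values are kept and counted in a message.
2. **Band cropping.** The extreme bands are noisy; analysis uses the inner
   975–1646 nm window (200 bands).
3. **Segmentation.** Seeds are bright against the black sampling plate at
   1200 nm, so a single-band threshold (Otsu by default; fixed for strict
   reproducibility) plus 8-connected component labeling isolates seed
   instances. Components smaller than 20 px are treated as plate debris.
   Labels are assigned in raster order of each component's first pixel so
   outputs are deterministic.
4. **Pixel-level preprocessing.** Each pixel spectrum is (a) denoised with
   a level-3 Daubechies-6 wavelet decomposition, (b) area-normalized
   (`x_i / sum_j x_j`), (c) smoothed with a 7-point moving average. The
   chain learns nothing from data, so it cannot leak information between
   splits.
5. **Classification.** A compact 1-D CNN maps a spectrum to three variety
   probabilities. Per-pixel argmax is *Decision-1*; a per-seed majority
   vote over pixel calls is *Decision-2*. The per-seed average of
   preprocessed pixel spectra supports a third, object-wise mode.

## The classifier

The network is
`conv(64, k=3, s=1, p=0) → ReLU → maxpool(2,2) → batchnorm →
conv(128, k=3) → ReLU → maxpool(2,2) → batchnorm → flatten →
dense(512, ReLU) → dense(128, ReLU) → dense(3) → softmax`.
For a 200-band input the feature lengths are 198 → 99 → 97 → 48, so the
flattened width is 48 × 128 = 6144. Training minimizes softmax
cross-entropy with plain SGD (learning rate 0.005, no momentum by
default), batch size 1024 for pixel spectra and 200 for average spectra,
reference epoch count 300.

There is no deep-learning runtime among the package's dependencies, so the
network — forward, backward, and the SGD loop — is implemented in C++
(RcppArmadillo). Convolutions are im2col matrix products in single
precision; all randomness (He-normal initialization, epoch shuffling)
flows from one `std::mt19937` seed, so training is reproducible
bit-for-bit on a given platform. Numerical conventions that the reference
description leaves open, and the defaults chosen:

* batch normalization follows pooling (the stated layer order), uses
  biased batch variance, eps `1e-5`, running-statistic momentum 0.1;
  evaluation mode uses the running statistics;
* weights use He-normal initialization (suited to ReLU stacks); biases
  start at zero;
* a trailing batch of size 1 is skipped during training (batch statistics
  are undefined for it); batch 1024 over realistic pixel counts never
  produces one;
* no early stopping: validation accuracy is recorded per epoch but never
  influences the weights.

## Majority vote

A seed's vote tally is the fraction of its pixels assigned to each
variety; the seed takes the variety with the largest fraction. Exact ties
break toward the lowest class index — a deterministic rule; with
tens-to-hundreds of pixels per seed, ties are measure-zero in practice.
If every class's per-pixel accuracy exceeds chance, the vote is a
majority filter whose error decays exponentially in the pixel count, which
is why seed-level accuracy dominates pixel-level accuracy in every
experiment mode.

## The wavelet step

The chemometric literature says "wavelet transform (Daubechies 6, level
3)" without fixing the operation. The package implements denoising:
soft-thresholding of all detail levels with the universal threshold
`sigma * sqrt(2 log n)`, `sigma` estimated per spectrum as
`MAD(finest details) / 0.6745`, with half-sample symmetric boundary
extension. A pure decomposition–reconstruction (`threshold = "none"`) is
the identity to machine precision and is available for sensitivity
checks. The transform's conventions (extension, downsampling phase,
multilevel length bookkeeping) follow the de-facto standard of PyWavelets,
and the test suite pins them against frozen reference coefficients.

Edge handling for the 7-point moving average: the definition is undefined
within 3 points of either end, so the package uses the mean over the
in-range part of the window, which preserves spectrum length and leaves
constant spectra unchanged. Reflect padding was considered and rejected:
truncation is the simpler rule with the same constant-preservation
property.

## The synthetic generator

Real instrument data for the seed application is not redistributable, so
the package ships a generator whose statistical structure mirrors what the
application reports, making every stage testable:

* a shared smooth base reflectance curve with peaks near 1109/1284 nm and
  valleys near 1204/1456 nm, built from Gaussian bumps on the 200-band
  grid (the "raw" 256-band variant extends the same grid by 29 bands below
  and 27 above, so cropping to 975–1646 nm returns exactly 200 bands — an
  endpoint-inclusive uniform 874–1734 grid would contain only 199);
* variety differences confined to a smooth bump at 1045 ± 28 nm, inside
  the 975–1120 nm window where real varieties differ; the three class
  means are collinear and equally spaced;
* a per-seed additive offset `N(0, seed_sd)` (biological seed-to-seed
  variation), a smooth multiplicative within-seed shading field (surface
  curvature/illumination), and iid per-band Gaussian pixel noise.

Because the class means are collinear and the noise Gaussian, the
Bayes-optimal per-pixel accuracy is available in closed form: projecting
onto the difference direction gives three equally spaced Gaussians
(spacing `D`, sd `sigma_t`), and the optimal rule's accuracy is
`(4 * pnorm(D / (2 * sigma_t)) - 1) / 3`. The projection noise combines
the pixel noise with the projected seed offset; the shading field is
excluded because area normalization removes multiplicative factors
exactly. `make_profiles()` calibrates the class spacing so that this
closed form equals 80% at `separation = 1` — a deliberately hard pixel
task. The defaults (`pixel_sd = 0.040` on reflectance around 0.45,
consistent with the sizable per-band SD envelopes real seed spectra show;
`seed_sd = 1.5e-3`; `shading_sd = 0.02`) put most of the projection variance
into pixel noise (at the calibrated spacing the class differences are ~5%
of the base reflectance, like the visibly-separated real varieties, which
is also what keeps the SGD gradient scale workable); keeping the
seed-level offset small is what makes
majority votes reliable even at 75–80% pixel accuracy, mirroring the
reported pattern where vote accuracy saturates near 100% while pixel
accuracy sits far below.

What the generator does **not** emulate: real within-seed spectral
heterogeneity (embryo vs cotyledon chemistry — the published prediction
maps show spatially structured, not iid, pixel disagreements), instrument
stray light and wavelength-dependent noise, partial-volume mixing at seed
boundaries (synthetic seeds have crisp edges, which is why segmentation
recovery is near-exact), and touching seeds. Passing tests therefore
demonstrate correctness of the pipeline's machinery and its statistical
behavior under a faithful-but-idealized noise model, not instrument-level
performance.

## Desk-scale protocol and problem sizes

The reference experiments use 810/180/900 seeds per variety and 300
epochs. The package's default protocol scales this to 60/20/60 seeds per
variety with 70–90 pixels per seed (~14,000 training pixels) and 60
epochs for pixel-wise models — about 1/13.5 of the seed counts, the same
ratio applied to epochs — so the full end-to-end run fits comfortably on a
single CPU. Object-wise models are three orders of magnitude cheaper, so
the training-size sweep keeps the reference 300 epochs. Full-scale
settings remain one argument away (`epochs`, `n_train`, ...).

One practical note on the object-wise sweep: with only tens of average
spectra, very low class separation, and plain SGD, the network can sit at
chance for hundreds of epochs (the informative signal is a ~1e-4 relative
perturbation of a large common mean). The sweep is therefore demonstrated
at a larger profile separation, where the size→accuracy trend is
expressed within the desk-scale budget; the pixel-wise end-to-end run
keeps the hard calibrated 80%-Bayes setting.

## Known limitations

* The CNN engine is CPU-only, single-threaded apart from BLAS, and
  implements exactly the fixed two-conv/three-dense topology (widths,
  kernel and pool sizes are configurable; depth is not).
* Bit-for-bit training reproducibility holds per platform (BLAS and
  libm implementations may differ across machines).
* ENVI I/O covers float32/float64 BIL/BSQ/BIP with wavelength metadata —
  the subset line-scan spectrographs emit — not the full ENVI dialect.
* Soft (probability-averaging) voting is not implemented; the decision
  stage is the hard majority rule.
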