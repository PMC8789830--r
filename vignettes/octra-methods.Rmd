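---
title: "Accelerated OCTA reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated OCTA reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

OCT angiography (OCTA) contrasts moving blood against static tissue by
comparing repeated B-scans acquired at the same slow-axis position: red
blood cell motion decorrelates the backscatter signal between repeats,
static tissue does not. Image quality therefore grows with the number of
repeats (it saturates around eight) and with the enface sampling
density — and so does acquisition time, linearly in the repeat count and
quadratically in the per-axis sampling density. A fully sampled, 8-repeat
volume that takes 17.8 s can be acquired in about 1.1 s if the scan step
is doubled and only two repeats are taken (a 16-fold speed-up), at the
cost of resolution and quality.

`octra` reconstructs the fully-sampled, high-quality (HR, HQ) enface
angiogram from its undersampled, low-quality (LR, LQ) counterpart with a
two-stage convolutional generator:

* a **super-resolution (SR) stage** that fills in the skipped raster
  positions (LR,LQ → HR,LQ), and
* a **quality-enhancement (QE) stage** that compensates the missing
  repeats (HR,LQ → HR,HQ).

Both stages share one template: a 9×9 convolution extracts low-level
features; a *Deep layer* of five 3×3 convolution blocks with PReLU
activations extracts high-level residuals; the two feature streams merge
by element-wise summation; the SR stage then upsamples with
pixel-shuffle stages (one conv + ×2 shuffle per factor of two) and both
stages finish with a 9×9 convolution. The Deep layer comes in two
wirings: **dense** (block *k* sees the channel concatenation of the
layer input and all previous block outputs; a 1×1 fusion convolution
restores the base width) and **residual** (each block's output is added
to its input).

## Training objective

Reconstruction is trained with a composite perceptual loss

$$L = L^{MAE} + 0.8\,L^{MS\text{-}SSIM} + 7\times10^{-5}\,L^{FMAE},$$

where $L^{MAE}$ is the mean absolute error, $L^{MS\text{-}SSIM} =
1-\mathrm{MSSSIM}(Y,\hat Y)$ preserves local contrast, and $L^{FMAE}$ is
the mean absolute difference of the 2-D Fourier magnitudes, which
penalizes the frequency-space remnants of undersampling. The MAE term
shapes the low frequencies; the two auxiliary terms recover
high-frequency vessel detail.

Training is **two-staged per batch**: the SR module is updated against
the (HR, LQ) intermediate, the QE module against the (HR, HQ) target
using the SR output *detached* (no gradients flow back), and the
concatenated network is then finetuned end to end at one tenth of the
learning rate. Weights are He-normal initialized and optimized with
Adam under early stopping and L2 regularization. An optional
**adversarial stage** then alternates a discriminator step on
$-[\log D(Y) + \log(1-D(G(X)))]$ with a generator step on
$L + 5\times10^{-3}(-\log D(G(X)))$, pushing reconstructions onto the
manifold of real high-quality angiograms.

## The synthetic phantom

No public dataset accompanies the method, so the package ships a
phantom generator whose statistics reproduce the one property every
stage depends on: *flow decorrelates between repeats, static tissue does
not*. A phantom is a set of correlated-random-walk centerlines dilated
to tubes (connected, curvilinear structures — exactly what the
skeleton-based connectivity metric needs; anatomical realism is not the
goal) over a smoothed-Gaussian speckle background. Each repeat adds
per-voxel Gaussian noise everywhere (`static_noise_sigma`, default
0.02 — the static decorrelation floor), and inside vessels a flow
component follows an AR(1) process with inter-repeat correlation
$1-$`flow_decorrelation` (default 0.7, i.e. strong but not total
decorrelation). Vessels sit 0.35 above the background with a 0.15 flow
amplitude; with the background at 0.35 ± 0.08 this gives vessels clear
but noisy contrast, qualitatively like a cortical-vessel enface slice.
Angiograms are formed as the mean absolute difference of adjacent
repeats, min–max normalized per volume (an all-constant volume maps to
zeros). The published pipeline defers the exact angiography algorithm to
earlier system work; the adjacent-pair estimator is this package's
stand-in and reproduces the one property used downstream — estimator
dispersion shrinks as repeats are averaged.

What the phantom does **not** model: speckle statistics of real OCT
interferometry, bulk motion, shadowing below large vessels, depth decay.
A passing test suite therefore certifies the pipeline's mechanics and
orderings, not in-vivo metric values.

## Pair construction and data handling

From an 8-repeat series, `make_pairs()` builds per-depth-slice training
records: the target from all 8 repeats; the low-quality intermediate
from one uniformly chosen *adjacent* repeat pair (a literal reading of
randomly selecting two sequential B-scans); the input from the same
repeat pair of the enface-downsampled series. Downsampling is **strided
subsampling** — a larger raster step skips positions, it does not
average them — so ratios compose (`r = 2` twice equals `r = 4`) and the
corner-pixel alignment convention makes interpolation baselines exactly
invertible by the same stride. Slices are retained by an automatic
vessel-content rule (fraction of pixels above a threshold), standing in
for the manual selection used on real data. Splits are seeded 9:1
shuffles (2000 images → 1800/200); augmentation draws from the 8-element
dihedral group only, so ground truth is never interpolated.

## Evaluation

`evaluate_pairs()` scores SSIM, MS-SSIM, PSNR, RMS contrast
(population standard deviation) and **vessel connectivity**: Otsu
binarization, Zhang–Suen thinning to a one-pixel skeleton, 8-connected
labeling, and the fraction of skeleton pixels in components of at least
5 pixels. The thinning and the 8-connected labeling are implemented in
the package (the labeling via an `igraph` pixel-adjacency graph; the
available image-analysis labeler is 4-connected, which would split
diagonal vessel runs). SSIM uses the standard 11×11 Gaussian window
(σ = 1.5), population statistics, and valid-region averaging; MS-SSIM
uses the standard five exponents, renormalized when an image supports
fewer dyadic scales. Identical images give infinite PSNR; such values
are flagged and excluded from summary means, as are undefined
connectivity values on empty foregrounds.

The acquisition model is analytic: undersampling both enface axes by
$r$ and using $n$ of 8 repeats speeds acquisition by
$r^2 \cdot 8/n$; times are reported to two significant figures (three
when the integer part needs them). With the 17.8 s baseline this gives
16× / 1.1 s, 64× / 0.28 s and 256× / 0.07 s, and ratios 4 and 8
correspond to 40 µm and 80 µm effective step sizes.

## Numerical engine and design choices

No deep-learning framework is available to R in this package's
dependency tier, so the networks run on a small reverse-mode autodiff
engine written here: eager tape, `(H, W, N, C)` tensors, convolutions as
BLAS-backed im2col GEMMs with a transposed-convolution input gradient,
and analytic custom gradients for the Fourier-magnitude loss (via the
adjoint DFT). Every primitive's gradient is tested against central
differences; the composite loss gradient agrees to better than 1e-4 on
8×8 instances. Further choices a maintainer should know:

* **Output clamping.** Data are normalized to `[0, 1]` and the module
  exits clamp to that range. The clamp uses a straight-through gradient
  during training; a hard-zero gradient would silence the roughly half
  of output pixels that saturate right after initialization.
* **MS-SSIM in the loss.** Five scales need images of at least 176 px;
  small training images reduce the scale count (the 48 px benchmark uses
  three) with the leading exponents renormalized. Scale means are
  clamped at 1e-6 before the fractional powers so rare negative
  contrast-structure values cannot produce NaNs.
* **Fourier MAE.** Unnormalized forward DFT, magnitude only (no log
  compression), divided by the pixel count once — the published form
  taken literally.
* **Discriminator.** Strided 3×3 stack doubling 64 → 512 channels with
  batch-statistic normalization and leaky ReLU (0.2), global average
  pooling, sigmoid. The exact published widths live in supplementary
  material that is not available; these are the standard
  super-resolution-GAN choices consistent with the figures.
* **Hyper-parameters.** The published values came from a random search
  whose results are not reprinted; defaults here (Adam 1e-4, finetune
  factor 0.1, batch 8, patience 10, L2 1e-5, PReLU slope 0.25
  per-channel) follow the same literature family and are all
  configurable.
* **Stand-ins decided where the source is silent:** the dense-variant
  fusion operator (1×1 convolution), per-channel PReLU, bilateral
  defaults (spatial σ 3 px, range σ 0.1), Lanczos order 3, early
  stopping applied to the adversarial stage through the generator's
  non-adversarial validation loss. The stated field of view (3 mm) and
  400 × 10 µm sampling do not reconcile exactly; the model records step
  size and point count and leaves the FOV figure alone.

## The desk-scale benchmark

`desk_scale_benchmark()` is the package's end-to-end experiment: 230
synthetic pairs at 48×48 HR and ratio 2 (200 train, 30 held out), small
two-block 8-channel generators in both wirings, three training seeds
each, three epochs of the two-staged schedule at Adam 2e-3 — sized so
one training takes about two minutes on a single CPU core and the whole
experiment stays inside a coffee break. Two orderings are asserted: the
dense generator's median held-out SSIM must exceed bicubic
interpolation's by at least 0.005 (in practice the margin is an order of
magnitude larger), and the dense wiring must not trail the residual
wiring's median by more than 0.01. These are the synthetic analogues of
the published sectioned-enface comparisons; the margins are asserted
weakly because three seeds of a two-minute training are noisy, and
nothing at this scale should be read as a claim about in-vivo values.

## Known limitations

* The phantom's simplicity means metric *values* on synthetic data do
  not transfer to tissue; only orderings and mechanics are certified.
* Registration and bulk-motion correction are out of scope (phantom
  frames are aligned by construction); real acquisitions need external
  motion handling first.
* The engine is CPU-bound R; it is sized for the benchmark and for
  method study, not for training 400×400 clinical models.
* Batch normalization uses batch statistics in all modes, so
  single-image discriminator outputs are batch-context dependent.
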