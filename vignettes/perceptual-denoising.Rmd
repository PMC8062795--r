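---
title: "Perceptual-loss speckle denoising and sharpness evaluation for OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptual-loss speckle denoising and sharpness evaluation for OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsharp)
```

## The problem

Optical coherence tomography (OCT) renders cross-sections of the retina as
B-scans, and every B-scan carries multiplicative speckle — coherent-imaging
noise that obscures the thin, horizontally layered structures (the retinal
layer boundaries) that clinicians and segmentation algorithms rely on. A
practical route to a clean reference is to register and average many
B-scans of the same location; a denoising network can then be trained to
map a single noisy B-scan to its averaged counterpart.

The choice of *training loss* shapes what such a network learns. Pixelwise
losses (L1/L2) reward average-intensity agreement and tend to produce
smooth, slightly blurred outputs in which faint boundaries fade. Measuring
the discrepancy instead in the activation space of a fixed convolutional
feature extractor — a *deep-feature (perceptual) loss* — rewards agreement
of structure and texture, trading a little pixel fidelity for crisper
boundaries. This package implements the full apparatus needed to study
that trade-off at desk scale: a residual denoiser, a tap-able feature
extractor, the loss algebra, the patch-based training protocol, a layered
phantom simulator, and a five-metric sharpness evaluation suite.

## The model

The denoiser is a DnCNN-style residual network: a stack of `depth`
convolutional layers (Conv+ReLU in, Conv+BatchNorm+ReLU hidden, bare Conv
out; stride 1, "same" padding) predicts the *noise residual* `R(x)`, and
the clean estimate is `x - R(x)`. Residual learning makes the identity
mapping trivially representable — zeroed weights return the input
unchanged, which `denoise()` guarantees and the tests assert. The default
geometry (17 layers, 64 filters of 3x3) matches the standard DnCNN
roster; toy geometries (depth 6-8, width 16-32) train in minutes on one
CPU and preserve every architectural contract.

The feature extractor follows the VGG-16 convolutional topology: five
blocks of 3x3 Conv+ReLU layers with widths 64/128/256/512/512 and 2x2
max-pooling between blocks. Features are read post-activation at the
standard taps `relu1_2, relu2_2, relu3_3, relu4_3, relu5_3` (the 2nd,
4th, 7th, 10th and 13th convolutions). Grayscale input is scaled to
[0, 255], replicated to three channels, and mean-centered with the
ImageNet channel means. The extractor is *frozen*: no training step ever
touches its weights (asserted bitwise in the tests); gradients flow
through it only to reach the denoiser. Pretrained weights can be supplied
from a file; absent one, the extractor uses seeded random initialization,
which exercises every code path and still yields a meaningful (if weaker)
structural loss signal.

### Loss algebra

A `loss_spec()` is declarative: coefficients for pixel L1/L2 terms plus a
named weight per feature tap, with optional per-channel weights
(LPIPS-style calibrated weights, loadable from a file). Pixel losses are
per-batch means of per-image *summed* norms; each feature term is
normalized by its tap's width x height x depth before weighting, and the
weighted terms are summed. `combined_loss()` reports a per-term breakdown
that sums exactly to the total, which is what the dual-loss convergence
monitoring plots.

Two conventions were genuinely open and are fixed as follows: the
all-tap "VGG" loss uses equal weights 1/5 per tap (the equal-weight
convention used when comparing feature distances), and per-tap
normalization happens *before* the weighted sum, consistent with the
combination being a weighted sum of per-layer losses.

## The synthetic data generator

`generate_phantom()` renders a layered retina-like cross-section:
horizontal bands of constant reflectivity (dark vitreous, alternating
bright/dim layers, a bright RPE-like band, dark choroid) separated by
smooth boundaries with sinusoidal waviness, a centered foveal depression,
and optional vertical vessel shadows. Boundaries are real-valued
per-column row curves; rendering uses linear sub-pixel coverage over one
row, because edge-width-based sharpness metrics need finite-width
transitions rather than degenerate single-row steps. Configurations that
would make boundaries cross or leave the image raise validation errors.

`apply_speckle()` implements fully developed multiplicative speckle with
a gamma number-of-looks model: each pixel is multiplied by an i.i.d.
`Gamma(shape = L, scale = 1/L)` factor (unit mean, variance `1/L`). The
default `looks = 4` gives the heavy granularity typical of single
B-scans; `n_frames = 8` frames are averaged into the reference, emulating
a registered-and-averaged acquisition with perfect registration. These
defaults are the package's standing study conditions. The `1/K` variance
law of frame averaging and the gamma moments are verified to Monte-Carlo
tolerance in the tests.

What the phantom does *not* emulate: physical OCT signal formation
(coherence, point-spread, depth attenuation), registration error between
frames, pathology, and the spatial correlation of real speckle (the
simulator's speckle is pixelwise independent). Passing tests therefore
demonstrate correctness of the machinery and the *direction* of effects,
not clinical performance.

## The sharpness evaluation suite

* **PSNR** — `10 log10(peak^2 / MSE)` in dB. "Peak" is deliberately the
  *declared dynamic range* of the reference (bit-depth convention), not
  the observed maximum, so a test image cannot change its own yardstick.
  Identical images return an `Inf` sentinel.
* **EPI** — per annotated boundary, the accumulated absolute
  *row-direction* difference `sum_j |I(i+1, j) - I(i, j)|` on the [0, 1]
  scale, with `i` the boundary row rounded to the nearest pixel. Only
  vertical differences are used because retinal boundaries are horizontal
  structures. EPI is deliberately reported per boundary and is known to
  be noise-sensitive: speckle inflates it, which the tests demonstrate.
* **PSI** — Sobel edge map (threshold: fraction 0.1 of the maximum
  gradient magnitude, configurable), edge widths traced pixelwise along
  the dominant gradient axis to the nearest local extrema, 32-px tiles,
  local sharpness = 1/(mean width in tile), pooled as the mean of the
  highest 22% of local values.
* **JNB** — 64-px tiles are *edge blocks* when >2% of their pixels are
  edge pixels; traced widths are normalized by a contrast-dependent
  just-noticeable width (5 below contrast 51 on the 0-255 scale, 3 at or
  above — a step function, since only the endpoints 3 and 5 are
  specified) and pooled with exponent `beta = 3.6` within blocks; the
  image score is `n_edge_blocks / (sum_b D_b^beta)^(1/beta)`, so less
  blur gives larger values.
* **S3** — per 32-px block (50% overlap), a spectral term maps the
  magnitude-spectrum slope `alpha` through
  `S1 = 1 - 1/(1 + exp(-3 (alpha - 2)))`, and a spatial term `S2` takes
  the maximum normalized total variation over 2x2 sub-blocks; the map is
  `S1^g * S2^(1-g)` (default `g = 0.5`) and the scalar is its maximum,
  together with the slope of the arg-max block.

### Numerical choices worth knowing

* **Spectrum slope estimation.** Each block is mean-removed, Hann
  windowed, DFT'd; the radial profile uses rounded-radius ring *means*
  (equivalent to polar resampling with a fixed number of orientation
  samples per frequency), and `log z(f)` is regressed on `log f` over
  `1 <= f <= Nyquist`. Mean removal matters: without it the DC component
  leaks through the window into the lowest frequency bins and biases the
  slope upward by several tenths. A ring *sum* instead of a mean would
  tilt every slope by about +1 (ring population grows linearly with
  frequency) and would break the recovery of constructed `f^-alpha`
  fields, which the tests check to within ±0.2. Constant blocks have an
  empty spectrum and return the `Inf` (maximally blurred) sentinel, which
  `S1` maps to 0.
* **Edge tracing.** Tracing walks one pixel at a time along rows (for
  horizontal edges) or columns (vertical) in the direction of increasing
  intensity to the first local maximum, and oppositely to the first
  local minimum; plateaus stop at their nearest end. Border pixels with
  no room to trace are excluded. A hard step yields width 1, a two-row
  ramp width 2, and Gaussian blur strictly widens mean widths — these are
  the anchors for PSI/JNB behavior. PSI and JNB keep both edge
  orientations (only EPI is restricted to horizontal boundaries);
  restricting them too would be a one-line change in `edge_map()` use.
* **Two printed-form ambiguities** in the metric definitions were
  resolved by directionality: local sharpness in PSI is `1/width` (any
  global block-count factor cancels in orderings), and JNB *divides* the
  edge-block count by the pooled distortion — both choices make "sharper
  image, larger score" true, which the blur-ladder tests then verify
  end-to-end: PSI, JNB and S3 are each strictly decreasing across
  Gaussian blur sigma in {0.5, 1, 2, 4} on a fixed 256x256 phantom.
* **Offset invariance.** All three no-reference metrics depend on
  gradients and traced widths only, so adding a constant to an image
  changes nothing (up to JNB's contrast banding at the cut, which the
  tests avoid by construction).

## Training protocol

`extract_patches()` lays a stride-45 grid of 180x180 patches (defaults)
with identical corners on the noisy and reference images; the closed-form
grid count holds for arbitrary sizes (a 999x868 B-scan yields 19 x 16 =
304 patches). `filter_patches()` removes patches without retinal
structure: a patch is kept iff its reference standard deviation is at
least 0.02 *and* at least 5% of its pixels exceed twice the background
level (estimated once as the mean of the darkest quintile of reference
pixels and cached on the patch set, making the filter idempotent). The
criterion itself is the package's own: it cleanly separates vitreous
patches from layered tissue in both the phantom and real scans, but no
claim is made that it reproduces any particular historical patch count.

`train_dncnn()` runs Adam (learning rate 0.001, mini-batch 128 by
default; toy presets use far smaller batches) over seeded shuffled
mini-batches. Every `val_every` steps the history records the optimized
loss *and* every configured monitor loss with gradients disabled — this
is what exposes the characteristic divergence where optimizing the pixel
loss drives the feature loss up while optimizing the feature loss pulls
both down. `train_select()` trains `repeats = 5` models from derived
seeds and keeps the highest validation-PSNR checkpoint. No augmentation
is applied anywhere. All randomness flows from one master seed: phantom
seeds, per-frame speckle streams (fixed offsets per frame index),
initialization and shuffling, so any run is bit-reproducible in
single-threaded mode.

## Scale of the shipped experiments

The test-suite and acceptance-script experiments are sized for a single
CPU: toy denoisers (depth 8, width 32) trained for 200 steps on 40x40
synthetic patches gain well over 2 dB PSNR on held-out phantoms, and the
matched-budget comparison (depth 6, width 16, 60 steps, 32x32 patches,
three seeds) reproduces the qualitative trade-off: the pixel-loss model
scores higher PSNR while the feature-loss model scores at least as high
on S3. With a randomly initialized extractor the sharpness direction is
advisory — random features are a weak proxy for pretrained ones, and a
reversal is reported rather than treated as a defect. Full-scale
conclusions require pretrained VGG-16 weights (user-supplied; never
downloaded implicitly) and clinical data, both outside the package's
scope.

## Known limitations

* The gamma number-of-looks speckle model is a stand-in; real OCT speckle
  statistics are instrument-dependent and spatially correlated.
* The pretrained-weights and LPIPS calibrated-weights files are inputs,
  not artifacts of this package; with random-init extractors the
  perceptual-loss advantage is attenuated.
* The batch-normalization layers use batch statistics in training and
  running statistics in evaluation (standard contract); very small toy
  batches make running statistics noisy, which slightly penalizes
  short-run evaluation PSNR but affects all compared losses equally.
* S3's pooling takes the literal maximum over the map, so a single
  sharpest block determines the scalar; this makes S3 sensitive to
  isolated high-contrast texture, including denoiser overshoot.
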