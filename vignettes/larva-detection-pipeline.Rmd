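---
title: "Multispectral larva detection: models, parameters and design choices"
author: "larvaDetect maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral larva detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chironomid (non-biting midge) larvae occasionally pass through drinking-water
treatment trains and reach tap water, where even single individuals are a
public-health concern. Continuous monitoring needs a detector that (a) works
on imagery a fixed multispectral camera can capture inside a plant, (b) runs
and retrains quickly enough for real-time deployment, and (c) distinguishes
chironomid larvae from visually similar organisms (yellow worms, mosquito
larvae). `larvaDetect` implements that full pipeline: spectral band
selection, larva localization and cropping, dataset augmentation, a compact
convolutional classifier trained from scratch, and a model-selection rule
that prioritises speed among models of equal accuracy.

# Pipeline overview

1. **Capture** — four co-registered 8-bit band images per scene: green
   (GRE, 550/40 nm), red (RED, 660/40 nm), red edge (REG, 735/10 nm) and
   near-infrared (NIR, 790/40 nm), nominally 1200 x 1200 px. No public
   image corpus exists for this setting, so the package ships a seeded
   synthetic generator with planted ground truth (below).
2. **Wavelet conversion** (`waveletTransform()`) — each band image is
   reduced to the approximation subband of a separable 2-D DWT and
   rescaled to 8 bits. Default: Haar, level 1 (the simplest transform
   consistent with the approach; `db2` and deeper levels are available).
3. **Band selection** (`bandContrastScore()`, `selectBand()`) — per band,
   `(max - median) / (IQR + 1)` over the wavelet image scores how sharply
   a narrow high-intensity feature stands out; captures vote for their
   best band and the majority wins. On larva scenes the green band wins:
   the larva is a small, bright, elongated feature there, while the other
   bands carry mostly noise.
4. **Localization and segmentation** (`splitChannels()`, `locateLarva()`,
   `cropCentered()`, `segmentCaptures()`) — the wavelet grid is rendered
   through a fixed colormap whose green channel is monotone in intensity;
   the larva coordinate is the G-plane global maximum; a 300 x 300 crop
   centered there (clamped at borders, never padded) becomes one sample.
   Captures whose `max(G) - median(G)` falls below a quality threshold
   (default 50) are rejected and logged.
5. **Augmentation** (`augmentDataset()`) — seeded random rotations,
   shifts, horizontal flips and zooms expand the dataset by an integer
   factor (default 4, originals included), with full lineage recorded.
6. **Training** (`trainCNN()`, `gridSearch()`) — a 10-layer CNN (three
   3 x 3 valid-convolution blocks with 16/32/64 filters, each followed by
   2 x 2 max pooling; dense 256; dropout 0.5; sigmoid output) trained
   with binary cross-entropy; data split 7:3.
7. **Evaluation and selection** (`classificationMetrics()`,
   `selectOptimal()`) — accuracy, precision, recall, F1, the confusion
   matrix and the probability RMSE `sqrt(mean((p - y)^2))`; among models
   meeting an accuracy floor, the fastest-training one is selected, with
   RMSE as tie-break.

# The synthetic-capture model

`generateCapture()` renders a scene as: flat background (default mean 30,
8-bit) + larva capsule + additive Gaussian noise (default sd 5), clipped to
[0, 255] and rounded. The larva is an anti-aliased capsule — a thick,
optionally bowed line segment — because larvae appear as narrow, elongated
columns at this scale; species profiles differ in their geometry ranges
(chironomid 55–85 x 4–8 px, the longest and thinnest; yellow worm
40–70 x 8–14; mosquito 30–55 x 5–10). The capsule's intensity lift over
background is `bandContrast[band] * 255`, with GRE drawn in [0.5, 0.7] and
the other bands in [0.05, 0.2], so the green band is always the most
discriminative by construction — that is the empirical regularity the
pipeline exploits, not something it must discover.

What the generator deliberately does **not** emulate: optics and lighting
(point-spread, vignetting, illumination gradients), water-surface effects,
multiple larvae per scene, occlusion, and non-larva debris. Tests passing
on synthetic scenes therefore demonstrate that the pipeline's machinery is
correct and that the classifier can exploit the intended contrast
structure; they do not certify performance on real plant imagery.

Determinism: every capture is generated from a single integer seed; dataset
generation derives per-capture seeds by the fixed rule
`(master + 1000003 * i) mod 2147483647`, so any capture can be regenerated
in isolation. Augmentation draw seeds follow the analogous rule with
stride 131071 per parent.

# Numerical and design choices

* **Wavelet rescale.** The approximation subband is min-max rescaled to
  [0, 255] per image. A constant subband has no range; it maps to
  `value / 2^level`, undoing the orthonormal filter gain so flat scenes
  keep their level. Odd-length signals are repeat-padded on the right.
* **Colormap contract.** How a single-band image acquires three channels
  is a genuine design gap; the package renders G = grid and
  R = B = 255 − grid. The pipeline only relies on G being monotone in
  wavelet intensity (so "bright larva" means "high G"); R and B are
  reflections kept for visual inspection.
* **Quantiles** use R's default type-7 linear interpolation, both in the
  per-column boxplot summaries and the contrast score. The `+ 1` in the
  contrast score's denominator guards constant bands against 0/0.
* **Rejection rule.** The attrition from raw to segmented counts is
  reproduced by `max(G) - median(G) >= threshold` (default 50). Note an
  important interaction: because each image is rescaled to the full 8-bit
  range, *noisy* larva-absent captures stretch their noise floor to that
  range and pass the filter — they become genuine label-0 samples —
  while *featureless* (near-constant) captures fail it. The filter
  removes captures with nothing to standardize on, not absent scenes.
* **Localization ties** break lexicographically (smallest row, then
  column); coordinates are 0-based (row, col) from the top-left
  everywhere. Border crops clamp the window inside the image rather than
  padding, so every emitted pixel is real.
* **Augmentation fill.** Pixels exposed by rotation/shift/zoom-out are
  filled by nearest-edge replication (the warp samples with clamped
  source coordinates, bilinear interpolation). Parameter defaults —
  rotation ±30°, shift ±10%, zoom ±20%, flip probability 0.5 — are
  recorded in the run manifest. "Four-fold" expansion counts the original
  as one of the four, which is the reading under which the segmented and
  augmented totals (169 → 676, 128 → 512, 94 → 376) are consistent.
  Augmentation happens before the train/test split to match those totals;
  since variants of one parent may then straddle the split, a
  lineage-aware split mode (`lineageAware = TRUE`) is provided for
  leakage-free protocols.
* **Classifier input** is the 3-channel 300 x 300 crop; the 298-px
  first-convolution output confirms unpadded 3 x 3 kernels. The loss is
  binary cross-entropy (standard for a single sigmoid unit), weights are
  Glorot-uniform, and Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-7) is the
  default optimizer; SGD and RMSprop are available for the optimizer
  comparison. Training is float32 throughout — the precision deep
  learning frameworks use — with all randomness (init, shuffling,
  dropout) drawn from one seeded generator, so runs repeat bit-exactly
  on a given BLAS.
* **Layer counting** follows the architecture table rows: conv, pool,
  conv, pool, conv, pool, flatten, dense, dropout, dense = 10.
* **Residual backbone.** The 101-layer backbone is realised as a shape
  walk over the standard layer graph (7 x 7/2 conv pad 3; 3 x 3/2 max
  pool pad 1; four bottleneck stages of 3/4/23/3 blocks, strides
  1/2/2/2; 2048 channels), no weights needed: a 300-px input gives the
  side chain 300 → 150 → 75 → 38 → 19 → 10 and flatten
  10² × 2048 = 204 800. Inputs under 32 px are rejected (the five
  stride-2 stages would collapse the map).
* **Instability flagging.** A run is unstable when its loss went
  non-finite, ever exceeded 4 x its initial value, or shows no net
  progress (trailing-quarter mean loss still above 90% of the first
  epoch's) — the signature of a learning rate that only oscillates
  around the chance plateau. Empirically, rates ≤ 1e-2 converge on the
  package's test problems and 0.05–0.1 oscillate, matching the tuning
  protocol's observation.
* **Grid search** covers epochs {200, 300} x learning rates
  {1e-5, 1e-4, 1e-3, 1e-2} by default (eight runs), ranking by
  validation accuracy then validation loss; diverged runs rank last
  rather than aborting the grid. The 30% test split doubles as the
  validation set. Early stopping is off: fixed-epoch training with the
  overfitting-aware epoch grid is the protocol.
* **Selection rule.** The narrative weighting of "RMSE and speed" is
  made concrete as: accuracy floor (default 1.0) → training seconds
  ascending → RMSE ascending. This is the only ordering consistent with
  preferring a fast compact CNN over a slower residual network with a
  (much) lower RMSE. Training speed is measured wall-clock and is
  hardware-dependent; it is never asserted against any reference number.

# Split arithmetic

`splitIndices()` takes exactly `floor(ratio * n)` training samples.
Stratified mode apportions that quota across classes by largest remainder,
so per-class skew is at most one (e.g. 676 balanced samples at 7:3 give a
473-sample training set, 237/236 by class). Classes with fewer than two
samples refuse to stratify.

# Problem sizes used by the test suite and acceptance script

Full-protocol sizes (hundreds of captures, 200–300 epochs) are a
plant-deployment scale. The package's own verification runs use smaller,
fixed problem sizes chosen once:

* unit tests exercise geometry and statistics on 128–256 px scenes and the
  trainer on 12 px toy tensors;
* the scaled detection check trains the full 300 x 300 architecture on
  84 + 84 captures (factor-2 augmentation; ≥ 50 validation crops per
  class) for 30 epochs at lr 1e-3;
* `scripts/acceptance.R` runs the same protocol at 100 + 100 captures.

At these sizes the task is still the study's regime — GRE contrast ≥ 0.5,
noise sd 5, well-separated classes — and the classifier reaches perfect
validation accuracy within a few epochs; 30 epochs leaves a wide margin.

# Known limitations

* The capsule scene model is intentionally minimal; no claim is made about
  real-water imagery, lighting robustness or multi-larva scenes (counting
  is explicitly out of scope).
* The quality-threshold rejection rule is a reconstruction: the original
  attrition criterion is undocumented, so the filter is parameterised and
  auditable (every rejection is logged with its score) rather than fixed.
* Probability RMSE is computed on the evaluation split; with confidently
  correct models it falls many orders of magnitude and its exact value is
  initialisation-sensitive — the selection rule therefore uses it only as
  a tie-break below accuracy and speed.
* An ImageNet-pretrained residual network and the YOLO detector family
  are deliberately outside the package: the first needs pretrained
  weights, the second is an external pretrained system; the backbone's
  shape contract is what the package reproduces.
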