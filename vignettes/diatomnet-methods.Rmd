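---
title: "DiatomNet: model, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DiatomNet: model, pipeline, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diatoms are unicellular algae whose silica cell walls (frustules) carry
species-specific ornamentation — striae, pores, and outline shape.  Species
composition of diatom assemblages is a standard bioindicator for water
quality, so automated classification of diatom photomicrographs is of real
practical use.  This package implements **DiatomNet**, a lightweight
convolutional neural network with three dimension-reduced inception modules
designed for 68-way diatom species classification on elongated 432×128 crops,
together with the full pipeline around it: crop extraction from polygon
annotations, horizontal normalization, flip augmentation, stratified
splitting, SGD training, support-weighted evaluation, and activation-map
inspection.  A procedural generator of diatom-like micrographs makes every
stage testable with no external data.

## The architecture and its accounting

The network is declared once as an `architecture_spec` — an ordered list of
layer records — and everything else (shape tracing, parameter counting,
network construction) consumes that declaration.  The canonical layer stack
is: 7×7/2 convolution (64), 3×3/2 max pool, cross-channel normalization, a
1×1 (64) + 3×3 (192) convolution pair, 3×3/2 max pool, then three inception
modules with branch widths (64, 96, 128, 16, 32, 32), (192, 96, 208, 16, 48,
64) and (384, 192, 384, 48, 128, 128), separated by 3×3/2 max pools,
finishing with a 6×2 global average pool, 40% dropout, and a 68-way linear +
softmax head.  Every convolution (including all inception branch
convolutions) carries a bias and is followed by ReLU; there is no batch
normalization.

```{r, eval = FALSE}
library(diatomnet)
spec <- default_diatomnet_spec()
trace_shapes(spec)
count_parameters(spec)$total_millions_2dp  # 1.85
network_depth(spec)                        # 10
```

Analytic shape propagation uses two conventions chosen because they are the
unique simple pair reproducing every printed intermediate size
(216×64 → 108×32 → 54×16 → 27×8 → 13×4): convolutions pad `floor(k/2)` on
each side ("same-like"), and the 3×3/2 max pools use no padding with ceiling
division (edge windows kept).  Sizes are quoted width-first throughout,
matching how such layer tables are conventionally printed; pixel arrays are
`[row, column, channel]`.

**The reconciliation pool.**  Inception modules preserve spatial size, yet
the published size after the third module is half its input (6×2 from 13×4).
Since 13×4 cannot feed a 6×2 global average pool producing 1×1, the default
spec inserts an explicit parameter-free 3×3/2 max pool after the third
inception module.  This reproduces every downstream size and leaves the
parameter total untouched.  Whether the original implementation used an
extra pool, strided branches, or simply printed a typo cannot be determined
from the description; the choice is recorded, not asserted as the original
authors' intent, and `default_diatomnet_spec(reconciliation_pool = FALSE)`
shows exactly which table rows disagree without it via
`validate_against_table()`.

**Parameter accounting.**  Closed forms per layer:
`k_h·k_w·c_in·c_out + c_out` for a convolution, `c_in·c_out + c_out` for the
linear head, the sum over the six internal convolutions for an inception
module.  The canonical spec totals 1,854,996 ≈ 1.85 M with 3 input channels
(1,848,724 ≈ 1.85 M with 1 channel, so the rounded total does not
disambiguate the unstated channel count; 3 is used because the source
micrographs are color photographs).  The constructed network's stored
parameter count is asserted to equal the analytic total exactly.

**Cross-channel normalization.**  The description names the layer but not
its constants; the GoogLeNet-lineage defaults are used (window 5, k = 2,
α = 1e-4, β = 0.75), placed once between the first max pool and the 1×1/3×3
stem pair.

## The network runtime

No deep-learning framework is available to (or wanted by) this package; the
forward and backward passes are written on dense linear algebra.
Convolutions run as im2col + GEMM through the system BLAS, with a direct
per-image GEMM fast path for 1×1/stride-1 convolutions; max pooling stores
argmax indices for its backward pass; the local-response-normalization
backward uses the exact analytic Jacobian.  All arithmetic is double
precision, which keeps central finite-difference gradient checks at the
1e-8 level (the suite enforces 1e-4).

Initialization is Glorot (Xavier) normal — zero mean, variance
`2/(fan_in + fan_out)` — with zero biases, matching the stated protocol.
Training is plain SGD with classical momentum
(`v ← μ·v − η·grad; w ← w + v`), mini-batches of 16 drawn in a
seed-determined shuffled order (the last short batch is kept), mean
cross-entropy loss, and early stopping.  The early-stopping criterion is
not specified in the source protocol beyond its existence; this package
monitors validation loss with patience 10, `min_delta` 0, and restores the
best-epoch weights.  Defaults (`train_config()`): learning rate 1e-4,
momentum 0.9, batch 16, at most 300 epochs.

Inference is a pure function of parameters and input: dropout acts only in
training mode, and argmax ties break toward the lowest class index.  Input
pixels are expected in `[0, 1]`; a network can be built with
`input_scaling = "centered"` to rescale them to `[-1, 1]` at the input
layer, recorded on the network object so training, evaluation, and
interpretation can never disagree about the convention.

## Preprocessing

"Normalize horizontally" is operationalized as principal-axis alignment:
the major eigenvector of the annotation polygon's centered vertex
second-moment matrix defines the object's orientation, the image is rotated
by its negative (bilinear interpolation, reflective boundary), and the crop
is the rotated polygon's bounding box.  The 180° ambiguity of a principal
axis is left as produced — the flip augmentations cover both senses anyway.
Pixels outside the polygon are replaced by the median intensity of a
2-pixel annulus just outside the boundary, so the network cannot key on
hard rotation borders.  Resizing to the canonical 432×128 (width × height)
is a direct bilinear rescale that does not preserve aspect ratio: the
target is a single fixed input size, and the source material quotes one
size for all crops.  Flip augmentation produces
`{original, vflip, hflip, vhflip}` — a Klein four-group — and exactly
quadruples every class.

## Splitting

`stratified_split()` assigns per class: `floor(0.70·n)` to training,
`floor(0.15·n)` to validation, remainder to test, then moves one unit into
any empty split from the largest one.  The published split totals
(2,115/459/453 original; 8,479/1,814/1,815 augmented) arise from an
unspecified per-class rounding convention and are not exactly reproducible;
this package fixes the convention above and checks sums and per-class
bounds instead.  Notably 8,479 ≠ 4 × 2,115, which implies the original
augmented dataset was split at the crop level, letting flip variants of one
specimen straddle training and test.  The splitter therefore keeps the four
variants of a source object in one split by default (leak guard) and offers
`group_variants = FALSE` to mimic crop-level splitting.

## Evaluation

Per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
`F = 2PR/(P+R)`; the summary metrics are support-weighted averages, and
"weighted accuracy" is read as overall accuracy — which equals
support-weighted recall by an algebraic identity the suite asserts on
random confusion matrices.  Per-class metrics with zero denominators score
0 and are flagged in the report.  The implementation is cross-checked
against caret's per-class metrics to 1e-12 on random matrices.

## Interpretability

`activation_map()` returns the spatial map of the most strongly activated
channel at a named depth: *early* (first stem convolution), *intermediate*
(second inception module), *deep* (last inception module).  "Most strongly
activated" defaults to the largest spatial sum; largest single response is
available by flag.  The layer description this follows names its layers
only qualitatively, and describes channel-activation inspection rather than
gradient attribution, so the maps here are activation-derived (no
Grad-CAM).  `heat_map()` bilinearly upsamples the deep map to input
resolution and min-max normalizes it; constant maps come back as zeros with
a flag rather than 0/0.

## The synthetic generator

`generate_dataset()` renders elongated capsules — rectangles with
(optionally mushroomed) semicircular end caps — at uniform orientations on
smoothly textured noisy canvases, without overlap, each annotated by its
exact boundary polygon.  Class identity controls interior intensity,
length/width ratio, stria spatial frequency and amplitude (sinusoidal bands
perpendicular to the major axis, fading toward the margins), and pore
density (minimum-separation dart throwing).  This mimics the *statistical*
structure the pipeline assumes — elongated textured objects at arbitrary
orientations with pixel-level boundaries and unbalanced classes — not
diatom optics: there is no focus blur, no illumination falloff, no
off-axis specimens, no occlusion.  Passing tests on synthetic data
therefore demonstrate pipeline correctness, not field performance on real
micrographs.

`easy_benchmark()` is the canonical desk-scale fixture: 5 classes × 100
crops rendered directly at 432×128 with strong joint separation — interior
intensities 0.12/0.32/0.52/0.52/0.70, all well below the ≈0.85 background
so every object contrasts clearly with its canvas, the equal-intensity pair
split by an order-of-magnitude stria-frequency difference (0.20 vs 0.04
cycles/px), and pore densities up to 4 per 1,000 px² — pre-split 70/15/15.  The classes are constructed to be easy on purpose: the fixture
exists to demonstrate that the training loop can drive this architecture to
high accuracy quickly, not to pose a hard recognition problem.

## Desk-scale training choices

Two parameters of the benchmark training run differ deliberately from the
published protocol, which was tuned for 300-epoch runs on the real 3,027
image dataset:

* **Input centering.**  With unit-scaled inputs and Glorot initialization,
  ReLU attenuation leaves head features with standard deviation ≈ 0.02, and
  a 1e-4 learning rate moves them negligibly within 20 epochs.  The
  benchmark run builds its network with `input_scaling = "centered"`.
* **Learning rate 0.02** (momentum 0.9, batch 16 unchanged) for the
  depth-reduced benchmark network — chosen from a coarse subset sweep as
  the largest rate that descends smoothly at this scale.

Both choices are per-run configuration, not changes to the architecture or
to `train_config()` defaults.  The depth-reduced network
(`reduced_diatomnet_spec()`: full stem + first inception module + global
average pool head) is used for desk-scale runs because the full
three-module network adds depth that only slows the demonstration without
changing what it demonstrates.

Problem sizes used by the suite: the learnability check trains the reduced
network on the full 500-crop benchmark for up to 6 epochs (with best-epoch
restoration); the demonstration pipeline (`run_demo()`) allows 8; gradient
correctness is checked by central finite differences on a ~270-parameter
spec exercising every layer kind; metric equivalence uses 100 random
confusion matrices.

## Numerical details and degenerate inputs

* Softmax subtracts the column maximum before exponentiation; cross-entropy
  clamps probabilities at 1e-12.
* Ceil-mode pooling drops a window that would start beyond the padded
  input; max pooling over a window ignores padded cells, so no `-Inf` can
  leak out.
* Zero-area annotation polygons are skipped with a warning and surfaced in
  the extraction summary; a class with fewer units than splits is an error
  naming the class.
* Argmax ties (prediction, channel selection) break toward the lowest
  index, making every reported index deterministic.
* All randomness flows from explicit seeds (generation, initialization,
  shuffling, dropout); library calls never disturb the caller's RNG state.

## Known limitations

* The synthetic generator's realism gap (above) means accuracy on it says
  nothing quantitative about the 68-species problem; reproducing the
  published headline accuracies requires the original dataset.
* The runtime targets single-CPU double-precision execution; there is no
  GPU path, mixed precision, or multi-device support.
* Aspect-ratio-destroying resize follows the source description; if real
  crops vary wildly in elongation, padding-based resizing might be
  preferable but would depart from the stated pipeline.
* The per-class split rounding of the original work is unknown; exact split
  totals are therefore out of reach by design, and only sums/bounds are
  asserted.
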