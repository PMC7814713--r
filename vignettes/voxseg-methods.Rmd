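---
title: "voxseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

voxseg builds semantic-segmentation pipelines for volumetric medical images
from interchangeable blocks.  This vignette records the scientific model
behind each block, the tunable parameters and their defaults, and the design
decisions taken where more than one reasonable construction exists.  It
states no empirical result that the package's tests and validation script do
not themselves compute.

## The pipeline model

A pipeline maps a cohort of subjects — each an image volume with voxel
spacing metadata and, for training, an integer label mask — to per-voxel
class predictions on the subject's original grid:

1. **Data input.** Samples are loaded through a *data interface* contract
   (`listSamples`, `load`, `savePrediction`).  A NIfTI-1 backend ships;
   other formats plug in via `registerDataInterface()`.  Only the header's
   per-axis zooms (voxel spacing, mm) are consumed; the affine's rotation
   component is deliberately ignored and arrays are processed in stored
   voxel order.  Canonical anatomical reorientation is out of scope and
   callers with oblique acquisitions must handle it upstream.
2. **Preprocessing**, in the fixed order clip → resample → normalize.
   Clipping first means interpolation can never re-introduce out-of-range
   intensities; normalizing last means the statistics describe the grid the
   model actually sees.  Labels are one-hot encoded at the model boundary.
3. **Decomposition** into full images, a deterministic overlapping patch
   grid, or random crops (training only).
4. **Model.** Any architecture satisfying the probability-field contract;
   the bundled one is a standard 2D/3D U-Net.
5. **Prediction**: overlapping grid → per-patch class probabilities →
   mean merge → per-voxel argmax → nearest-neighbour restoration of the
   pre-resampling grid → write-out through the data interface.

## Preprocessing

* **Clipping** to an intensity window (e.g. a CT Hounsfield window such as
  [−79, 304] for kidney studies) is idempotent and elementwise.
* **Normalization** is per channel.  Z-scoring uses the *population*
  (divide-by-n) standard deviation; a constant channel maps to zeros rather
  than NaN.  Min-max modes project the observed range to [0, 1] or [−1, 1].
* **Resampling** to a target spacing computes the output shape per axis as
  `round(n · spacing/target)`, minimum 1.  Images are resampled separably,
  one axis at a time, through a dense interpolation-weight matrix.  The
  default kernel is Keys cubic convolution (Catmull–Rom, a = −0.5): an
  interpolating order-3 scheme that needs no prefilter pass, which is why it
  was preferred over a prefiltered cubic B-spline; `"linear"` and
  `"nearest"` are available.  Coordinates map voxel centers
  (`x_in = (i_out − ½)·n_in/n_out + ½`) and borders replicate.  Label masks
  are always resampled nearest-neighbour — the only label-preserving choice —
  and the pre-resampling grid is recorded so predictions can be mapped back.
* **One-hot encoding** is applied uniformly, including binary problems, so
  every loss sees the same class axis; decoding is the per-voxel argmax with
  ties broken toward the lowest class index (a deterministic, documented
  rule).

## Patch analysis

Window starts per axis run `0, S, 2S, …` with stride `S = P − O`; when the
last regular window stops short of the boundary, one extra *edge-aligned*
window at `shape − P` is appended.  This guarantees complete coverage
without zero-padding — padding would feed invented voxels into the model and
contaminate normalization statistics — at the cost of a boundary window that
overlaps its neighbour more than `O`.  Patch counts therefore may differ at
boundaries from implementations that pad.  Windows are 0-based and
half-open.

Overlapping predictions are merged by the arithmetic mean of each voxel's
class probabilities over all windows containing it, with separate sum and
count accumulators in double precision, making the merge invariant to patch
order to better than 1e−12.  Because the mean of identical one-hot vectors
is the vector itself, extract → merge → decode is exactly lossless on ground
truth — the property the test suite uses as the module's flagship check.
Gaussian-weighted blending is a known alternative and deliberately not
implemented.

Training-time patch sources: the deterministic grid (with blank-patch
skipping: windows whose label content is pure background carry no gradient
signal for the foreground classes and are dropped) or random crops.  Crops
alternate between two samplers: uniform offsets rejection-sampled toward
foreground (up to 10 draws, then the last draw is accepted regardless —
unconditional rejection could loop forever on empty masks), and
class-balanced crops centered on a voxel of a *uniformly chosen* foreground
class — class first, then voxel, so a 100-voxel lesion is sampled as often
as a 2000-voxel organ.  Without the balanced sampler, rare classes can
take many more epochs to converge because most uniform crops carry no
gradient signal for them.

## Data augmentation

Eight operators, each firing independently with its probability, in the
fixed order mirror, rotation, scaling, elastic deformation, brightness,
contrast, gamma, noise.  Spatial operators resample image and labels
through the *same* inverse coordinate map (image: multilinear with edge
clamping; labels: nearest-neighbour), so the label set can never grow.
Elastic fields are the classic construction: per-axis white Gaussian noise,
Gaussian-smoothed (width `elasticSigma`, default 8 voxels), rescaled to a
maximum displacement (`elasticAmplitude`, default 2 voxels).  Intensity
operators touch the image only: brightness adds an offset expressed as a
fraction of the intensity sd, contrast scales about the mean (mean
preserved), gamma maps min-max-normalized intensities through `x^γ` and
restores the range, noise adds i.i.d. Gaussians.

Defaults (probability 0.15 per operator; rotation ±15°, scale [0.85, 1.15],
gamma [0.7, 1.5], contrast [0.75, 1.25], brightness ±0.1·sd, noise sd up to
0.05) are the package's own choices, set conservatively so that augmented
phantoms stay within the intensity structure the classes are defined by;
they cannot be traced to a published parameterization and are all
overridable in the configuration file.  Translation augmentation is
realized implicitly by random cropping rather than as a resampling
operator — the two are equivalent up to boundary handling.  Augmentation is
training-only by design; there is no prediction-time augmentation.

## Losses and metrics

With one-hot truth `t` and predicted probabilities `p`, summed over voxels:

* **soft Dice** (pooled): `(2·Σtp + ε) / (Σt + Σp + ε)`;
* **class-wise Dice**: the same per class, with the mean reported
  alongside — the recommended view under class imbalance, where the pooled
  score is dominated by background;
* **Jaccard**: `(Σtp + ε) / (Σt + Σp − Σtp + ε)`, related to Dice by
  `J = D/(2 − D)`;
* **Tversky index** per class:
  `TI_c = (TP_c + ε) / (TP_c + α·FP_c + β·FN_c + ε)` over soft counts,
  loss `1 − mean_c TI_c`.  Defaults α = 0.3, β = 0.7 weight recall above
  precision, countering foreground under-segmentation; α = β = 0.5 recovers
  the class-wise Dice loss exactly (an identity the tests verify at
  vanishing ε);
* **cross-entropy − soft Dice**: `−(1/N)·Σ t·log p − D`, probabilities
  clipped to [1e−7, 1−1e−7].  The sign convention (difference, not sum)
  makes a perfect prediction approach −1.

Smoothing uses ε = 1e−5 throughout.  A consequence worth knowing: a class
absent from both truth and prediction scores `ε/ε = 1`, which inflates
class-wise means when classes are missing.  Training losses need analytic
gradients; Tversky, class-wise-Dice and cross-entropy gradients are
hand-derived and finite-difference-checked in the tests.  Custom metrics
register by name and may supply a gradient to become training losses.
Batch reduction is the mean over batch members.  Surface-distance metrics
(Hausdorff, ASSD) are out of scope.

## The U-Net and its native engine

The bundled architecture is the standard encoder–decoder U-Net: per level
two convolutions (kernel 3 per axis, "same" padding) each followed by
optional batch normalization and ReLU, optional dropout per block, 2×
max-pool downsampling with filters doubling from `baseFilters`; a matching
decoder with kernel-2 stride-2 transposed convolutions and skip
concatenation from the same-level encoder; a final 1-per-axis convolution to
C channels under a per-voxel softmax.  The softmax (rather than independent
per-class sigmoids) is the multi-class generalization that makes the output
a probability field: non-negative, summing to 1 per voxel — the contract
every registered architecture must honor.  Every input axis must be
divisible by `2^depth`; violations raise a configuration error naming the
axis.

Because no deep-learning backend is assumed, the package carries its own
CPU engine: tensors are `(voxels × channels)` matrices, convolutions are
gather (im2col) + BLAS matrix products with precomputed, memoized neighbor
index tables per resolution level, and all gradients are hand-derived
(finite-difference-verified to ~1e−8 in the tests).  Weights use He-normal
initialization seeded from the pipeline seed; optimization is Adam
(β₁ = 0.9, β₂ = 0.999) at a constant configurable learning rate — schedules
and early stopping are extension points, not features.  This engine is
sized for desk-scale patches (≈10⁴–10⁵ voxels); it is not a GPU substitute.
Model serialization is a plain `.rds` of the architecture name,
configuration and weights; custom architectures must be re-registered
before a loaded model can predict.

## Batches, caching, training loop

Items are bundled into `ceiling(n/batchSize)` batches whose concatenation
preserves item order; only the *processing order* of batches is shuffled
each epoch, deterministically from `(seed, epoch)`.  In disk-cache mode
each epoch's prepared batches are staged as one file per batch with a
tab-separated manifest; on-the-fly mode keeps them in memory.  Both modes
feed bit-identical voxel content — the tests compare the resulting fits at
1e−12.  In crop mode one epoch is `cropsPerSample` random crops per
training sample, a package decision.  The per-epoch loss and monitored
metrics are appended to a tab-separated history (columns epoch, split,
metric, value).

## Evaluation harness

Split modes: k-fold (test sets partition the ids; the first `n mod k` folds
take the extra sample), leave-one-out, percentage/hold-out (one mechanism:
a single fold at the given training fraction), and detailed (explicit lists
copied verbatim).  All random modes draw from the split seed.  Per fold a
fresh model is built and fitted on the training ids only; test predictions
are scored with the registered metrics, so cross-validation values are by
construction identical to direct metric calls on the same pairs.  Reports
are tab-separated (per-sample rows, per-fold means, a cross-fold mean).
Dataset statistics report per-sample intensity ranges and exact per-class
voxel counts and fractions.  Overlays are static per-slice PNGs (fixed
class palette, alpha 0.4, optional side-by-side truth); animated export is
out of scope.

## The phantom generator

`generatePhantom()` emulates the class structure of abdominal CT tumor
segmentation at desk scale: a dominant background (class 0), an "organ"
ellipsoid (class 1) at a random interior position, and a smaller "lesion"
ellipsoid (class 2) rejection-sampled (≤ 100 tries) to lie fully inside the
organ; intensities are strictly ordered class means (0, 0.5, 1.0) plus
white Gaussian noise (sd 0.05), on a 32³ grid with unit spacing by default.
Ellipsoid sizes (organ semi-axes 6–10 voxels, lesion 2–4) keep the class
frequency ordering background ≫ organ ≫ lesion, mimicking clinical
imbalance.

What the phantom deliberately does *not* model: anatomical shape variation,
CT physics (beam hardening, partial volume, HU calibration), intensity
overlap between classes, and inter-scanner variability.  A noiseless
phantom is exactly threshold-separable, and at sd ≤ 0.1 of the smallest
class gap nearly so; passing the end-to-end tests therefore demonstrates
that the pipeline machinery (preprocessing, patching, training dynamics,
merging, restoration) is correct and that the model can exploit a clean
intensity signal — it does not demonstrate clinical-grade segmentation on
real CT data.

## Validation problem sizes

The package's own end-to-end validation (test suite and
`scripts/acceptance.R`) trains the tiny configuration — 16 training and 4
held-out 32³ phantoms, U-Net with 8 base filters, depth 2, batch
normalization, batch size 2, 16³ patches with 8³ prediction overlap,
Tversky loss, 40 epochs of Adam at 1e−3 — chosen so the full study runs in
minutes on one CPU while leaving headroom above the 0.80 mean class-wise
Dice bar the tests assert.  Batch normalization matters here: without it
the small lesion class often fails to converge within this budget.

## Known limitations

Single-process CPU training only; no learning-rate schedules or early
stopping; no DICOM backend (the interface contract supports adding one); no
Gaussian-weighted patch blending; orientation metadata beyond zooms is
ignored; the evaluation harness offers no significance testing across
folds.
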