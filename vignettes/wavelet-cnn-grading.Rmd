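---
title: "Wavelet CNN grading of diabetic retinopathy: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet CNN grading of diabetic retinopathy: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diabetic retinopathy (DR) is graded from fundus photographs on the
five-point ICDR scale: 0 (no apparent retinopathy) through 4
(proliferative DR). The visual evidence is small and multi-scale —
microaneurysms a few pixels wide, exudates and haemorrhages spanning
larger patches — which makes a fixed-receptive-field classifier a poor
fit. This package implements a grading pipeline whose core idea is to
weave an exact multiresolution analysis (MRA) into a convolutional
network, so that every dyadic scale of the image is presented to the
network explicitly rather than having to be rediscovered by learned
kernels.

## Multiresolution analysis woven into a CNN

A single MRA level splits a plane $X_{l,t}$ with a low-pass
(scaling) filter $k_l$ and a high-pass (wavelet) filter $k_h$, each
application followed by dyadic downsampling:

$$X_{l,t+1} = (X_{l,t} * k_l) \downarrow 2, \qquad
  X_{h,t+1} = (X_{l,t} * k_h) \downarrow 2 .$$

Iterating on the low-pass plane yields the familiar sub-band pyramid. A
plain CNN with strided convolutions computes only the first recurrence
with a generic learned kernel — it discards the detail planes $X_{h,t}$
at every scale. The wavelet CNN restores them: the four Haar sub-bands
(LL, LH, HL, HH) of the input are computed at every level and
concatenated channel-wise into the feature maps of matching spatial
size, with a 1×1 projection shortcut restoring the running channel
width after each concatenation.

### Transform conventions (fixed once, used everywhere)

* **Filters.** Orthonormal Haar: $k_l = (1/\sqrt2, 1/\sqrt2)$,
  $k_h = (1/\sqrt2, -1/\sqrt2)$. The orthonormal convention is what
  makes the test suite exact: Parseval's identity and perfect
  reconstruction hold to floating-point precision, so the package can
  assert them at `1e-10` rather than "approximately".
* **Downsampling phase.** $\downarrow 2$ keeps even positions
  (0-based). For the two-tap Haar pair this tiles the plane into
  non-overlapping 2×2 blocks, so no boundary extension is ever needed;
  inputs must have even dimensions (and be divisible by $2^T$ for a
  depth-$T$ decomposition; the preprocessing chain guarantees
  $224 = 14 \cdot 2^4$).
* **Sub-band naming.** The first letter is the filter applied along
  image rows (axis 1), the second along columns: `lh` is low-pass
  vertical / high-pass horizontal. The fast path and the brute-force
  oracle used in the tests share this one convention.
* **Colour policy.** Channels are decomposed independently and the
  sub-bands stacked channel-wise, so each injection adds
  $4 \times C$ channels for a $C$-channel input. Which channel
  policy the original design used is not documented anywhere we could
  find; per-channel decomposition preserves all colour information
  and keeps the transform exactly invertible.

## The architecture

`wcnn_config()` describes the network: VGG-style 3×3/pad-1
convolutions, stride-2 3×3 convolutions in place of pooling, batch
normalisation before every ReLU, one sub-band injection per
decomposition level, a 1×1 projection after each injection, global
average pooling (GAP), and a linear 5-way head.

The published description of this architecture gives its construction
rules but not a width table; the only architectural pin is the total of
11,799,109 trainable parameters for the 224-pixel, 4-level, 5-grade
configuration. We therefore chose a near-doubling width ladder in the
VGG spirit and calibrated it once against that total:

| stage | layers | width |
|---|---|---|
| 0 (224 → 112) | conv 3×3, conv 3×3 s2 | 72 |
| 1 (112 → 56)  | inject L1 (+12), proj 1×1, conv 3×3, conv 3×3 s2 | 144 |
| 2 (56 → 28)   | inject L2 (+12), proj 1×1, conv 3×3, conv 3×3 s2 | 312 |
| 3 (28 → 14)   | inject L3 (+12), proj 1×1, conv 3×3, conv 3×3 s2 | 696 |
| 4 (14)        | inject L4 (+12), proj 1×1, conv 3×3, GAP, head | 517 |

Counting every convolution weight and bias, batch-norm scale and shift,
and the head gives exactly 11,799,109; the table is frozen in the
package defaults and asserted in the tests. The GAP feature dimension
of the full model is therefore 517. The fixed Haar filters are not
trainable and are never counted.

```{r, eval = FALSE}
library(waveletDR)
net <- build_network(wcnn_config())
count_parameters(net)      # 11799109
wcnn_layer_table(net)      # the audited table above
```

### Training choices

* **Loss and optimiser.** Softmax cross-entropy minimised by Adam. The
  learning rate defaults to Adam's conventional 1e-3; only the choice
  of optimiser is pinned by the source design, not its rate.
* **Batch normalisation.** Placed before each activation; the
  nonlinearity itself is unnamed in the source and we use ReLU, the
  default of the VGG family it imitates. BN uses $\epsilon = 10^{-5}$
  and running-statistic momentum 0.1.
* **Early stopping.** The published run reports early stopping without
  criteria. We monitor training accuracy with patience 5 and restore
  the best-scoring weights. Training accuracy (not a validation split)
  is monitored because the downstream protocol consumes the network
  only as a feature extractor; its own generalisation is measured by
  the classical heads on the held-out split.
* **Determinism.** Weight initialisation is seeded per model config and
  shuffling per train config; those are the only random sources, so a
  rerun with the same seeds reproduces the history bit for bit. The
  numerical engine is plain R (flat matrix layout + BLAS products), so
  no nondeterministic kernels exist. Evaluation-mode forward passes use
  running BN statistics and are deterministic by construction.

## Classifier heads and evaluation

The network is used as a feature extractor: the GAP vector of each
image feeds one of four heads — an RBF-kernel SVM, a random forest,
gradient-boosted trees, or a multinomial softmax head. The tree
ensembles default to 10 estimators, the value the source protocol fixed
against overfitting. The SVM defaults to $C = 1$ and
$\gamma = 1/d$; no values are published, so the conventional defaults
plus a small cross-validated grid-search utility
(`svm_grid_search()`) are provided. Margin-based heads (SVM, softmax)
standardise features internally — column means and standard deviations
are stored at fit time and replayed at prediction.

`compute_metrics()` implements the evaluation suite directly: per-class
one-vs-rest TP/FP/TN/FN, precision, recall and F1; their unweighted
macro averages (a 5-class problem reported with single values needs an
averaging convention, and macro is the one we document as the
headline); overall accuracy as the confusion-trace ratio; and
one-vs-rest ROC curves by threshold sweep with trapezoidal AUC, macro
averaged. Degenerate cases are explicit: a class never predicted gets
precision 0 with a warning; a class absent from the truth gets `NA`
recall/F1/AUC and is excluded from macros with a warning. The test
suite cross-checks the AUC against an independent implementation
(pROC) and asserts the arithmetic identities (accuracy = trace/total,
F1 = harmonic mean) to 1e-12.

## Preprocessing, balancing, splitting

* **Contrast enhancement.** Fundus images have low vessel/background
  contrast. The enhancement method is unnamed in the source, so the
  default is CLAHE on the luminance channel (clip limit 2, tile grid
  up to 8×8, reduced to divisors of the image side), with a plain
  linear stretch as the alternative. Both are deterministic and clip
  to $[0,1]$.
* **Resize and crop.** Images are resized to 256×256, then a random
  224×224 crop plus random horizontal flip in training mode, or a
  centre crop without flip at evaluation/feature-extraction time. Crops
  are seeded per image; the desk-scale configuration scales the pair to
  72 → 64.
* **Balancing.** Classes are up-sampled to the majority count by
  adding augmented copies — never by deleting records. Each augmented
  record stores a replayable descriptor (flip, width/height shift
  ±10%, zoom 0.9–1.1, nearest-border fill); re-rendering it is
  bit-exact. The magnitudes are conventional defaults, the named
  operations are pinned.
* **Order of operations.** Split first (stratified 80/20, per-class
  rounding, seeded, order-invariant), then balance the training
  partition only. Whether the original protocol balanced before or
  after splitting is unstated; balancing after splitting is the choice
  that cannot leak augmented near-duplicates of test images into
  training, so test metrics are always computed on original images.

## The synthetic phantom generator

Real fundus corpora cannot be bundled, so the package generates its own
study material: a bright disc with radial shading on a dark background,
seeded smooth vessel curves, and three lesion vocabularies rendered as
Gaussian profiles — small dark red dots (microaneurysm-like), bright
yellowish blobs (exudate-like), larger dark red blobs
(haemorrhage-like). The grade ladder places (0, 3, 8, 16, 28) lesions
at grades 0–4, split across the three types, with sizes growing 15% per
grade; grade 0 is always clean. Within-disc intensity variance is
strictly increasing in grade (a tested property), which is the
separability signal the downstream pipeline learns.

What the phantoms do **not** emulate: camera vignetting and exposure
artefacts, anatomical landmarks (optic disc, macula), lesion texture,
inter-patient variability, ungradable images. A pipeline that grades
phantoms perfectly has demonstrated that its plumbing — transform,
architecture, training loop, feature extraction, heads, metrics — is
correct and end-to-end learnable, not that it reaches clinical accuracy
on real retinas. The published full-corpus results require the original
data and long GPU training and are out of scope here.

## Desk-scale study conditions

All tests and the worked examples run on one CPU at a deliberately
small problem size: 50 phantoms per grade at 64×64 pixels, a 2-level
decomposition with widths (24, 48, 96) (≈ 8.4 × 10⁴ parameters —
the same architecture generator as the full model, just narrower),
at most 30 training epochs with batch size 25, stratified 80/20
hold-out, and all four heads compared. Under these conditions the best
head exceeds 0.9 macro-F1 on the held-out phantoms; the full-size
(11.8 M parameter) network is instantiated for the architecture audit
and parameter count but not trained.

## Numerical notes and limitations

* Two-tap filters only: the transform module deliberately supports the
  Haar family alone, because exactness (no boundary handling) is what
  the test contracts rely on; other wavelet families would need
  boundary-extended transforms.
* Convolution bias vectors are retained even though BN immediately
  follows (their gradient is absorbed by the BN shift); they are part
  of the parameter count convention, matching the common
  framework-default counting.
* Ties in `max.col` hard predictions are broken by first index;
  seeded heads make this reproducible.
* The pure-R engine favours auditability and determinism over speed;
  the full-size model supports forward passes (seconds per image) but
  is impractical to train in R — by design, since every tested claim
  lives at desk scale.
* `wcnn_e2e()` preprocesses training images once (seeded crop/flip at
  load time) rather than re-augmenting per epoch; with the phantom
  generator's lesion contrasts this is sufficient for the training
  accuracy to saturate, and it keeps every epoch's input identical for
  the determinism contract.
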