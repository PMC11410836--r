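---
title: "Automatic foot goniometry by bone-axis heatmap regression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic foot goniometry by bone-axis heatmap regression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneaxis)
```

## The measurement problem

The hallux valgus angle (HVA) and the first-second intermetatarsal angle
(IMA) are the standard radiographic parameters for grading hallux valgus
deformity on weightbearing dorsoplantar foot radiographs. Both are defined
from *bone axes*: the longitudinal midlines of the first proximal phalanx
(PH1) and the metatarsals (MT1-MT5), drawn between endpoints placed at the
ends of each bone region. HVA is the angle between the PH1 and MT1 axes;
IMA is the angle between the MT1 and MT2 axes. Manual goniometry is slow
and shows inter-rater differences of a few degrees; errors under 3 degrees
are conventionally considered good for manual measurement.

`boneaxis` implements an automatic pipeline:

1. **Axis encoding.** Expert-drawn axis segments become 6-channel
   probabilistic heatmaps (one channel per bone).
2. **Heatmap regression.** A five-level encoder-decoder convolutional
   network maps a standardized radiograph to the six heatmaps.
3. **Axis extraction.** Each predicted channel's high-value area is fitted
   with a total-least-squares principal axis, giving the bone's
   inclination angle.
4. **Angle derivation.** HVA and IMA are signed differences of
   inclinations.
5. **Validation statistics.** Agreement with (simulated) manual raters:
   MAE against the rater median, a one-tailed non-inferiority t-test
   against the 3 degree margin, error bands, inter-rater difference
   statistics, and the t-test power analysis for cohort sizing.

A key property of the heatmap formulation is that channels are
*independent*: overlapping bone regions — common in the crowded forefoot —
simply produce overlapping probabilistic bands, where segmentation-based
approaches break down because each pixel must belong to one label.

## Conventions

Images are matrices indexed `[x + 1, y + 1]` with the origin at the
top-left pixel center and y increasing downward. Angles are measured
counterclockwise (as seen on screen) from the right-facing horizontal;
internally all angle computations flip to a y-up frame so the sign
convention matches the visual one. Angles and their differences are
wrapped to (-180, 180], with ties at 180 resolved to +180.

Axes are directed proximal-to-distal (heel to toe). In a toes-up
dorsoplantar image all six inclinations then sit near +90 degrees, and HVA
= PH1a - MT1a and IMA = MT2a - MT1a are small signed differences. The
choice of direction is a package convention — a consistent direction is
required for signed differences, and either choice yields the same
magnitudes. Left and right feet are mirror images, so left-foot angle sets
are reflected (`theta -> 180 - theta`) onto the right-foot convention by
`normalize_side()` before comparison; clinical reporting uses `|HVA|` and
`|IMA|`, while signed values are retained internally.

## Heatmap encoding

For each bone the axis segment is rasterized to a 1-pixel 8-connected
line, thickened to a 5-pixel-wide band by morphological dilation with a
disc-shaped element, and smoothed with an isotropic Gaussian. The Gaussian
standard deviation scales with the image height `h` and inversely with the
segment length `L`:

* PH1: `sigma = h / (2.5 L)`
* MT1-MT5: `sigma = h / L`

so short bones in large images receive proportionally wider probabilistic
bands. The formula is read as `h / (2.5 L)`; the alternative reading
`(h / 2.5) L` would give standard deviations of thousands of pixels and
is dismissed as an interpretation artifact.

Design choices worth recording:

* **Rasterization** steps one pixel along the dominant axis and takes the
  minor coordinate from the *exact* line equation rather than from
  integer-rounded endpoints. Rounding the endpoints first biases the angle
  of a 50-pixel segment by up to ~0.8 degrees, which alone would consume
  the 0.5 degree round-trip tolerance the package holds itself to.
* **Thickening** uses a disc-shaped 5x5 element (the EBImage disc brush).
  Any isotropic element also extends the band slightly lengthwise; only
  the 5-pixel cross-section is specified.
* **Blurring** uses a separable truncated Gaussian (radius 4 sigma)
  applied as banded Toeplitz matrix products. This keeps the boundary
  semantics exactly "outside is black" and is numerically identical (to
  machine precision) to FFT-based blurring of a zero-padded image, while
  being several times faster at 512 px.
* **Renormalization.** Each channel is rescaled to peak 1 after blurring,
  making the regression target scale-invariant across bone lengths.
  Values are clamped to [0, 1].

## Network and training

The regressor is a U-net-style encoder-decoder with five resolution
levels: one 3x3 convolution + ReLU per encoder level with 2x2 max pooling
between levels, a mirrored decoder with nearest-neighbour upsampling and
skip-connection concatenation, and a 1x1 convolution with a sigmoid
bounding the six output channels to [0, 1]. Filter counts double per
level from `base_filters`. The loss is the per-image RMSE over all pixels
and channels, averaged over the minibatch; optimization is Adam. The
internal block composition (convolutions per block, activations,
normalization) is a package design choice — standard encoder-decoder
practice with the lightest block that meets the package's accuracy
targets; the sigmoid head matches the [0, 1] heatmap targets.

The network, its gradients, and the training loop are implemented in
C++ (RcppArmadillo) with im2col GEMM convolutions; analytic gradients are
verified against finite differences in the test suite.

Two numerical details matter in practice:

* **Output-bias prior.** The sigmoid head's bias is initialized to -2.5,
  the logit of the typical heatmap foreground mass (~5-8% of pixels).
  With a neutral initialization the first optimizer steps slam the output
  toward the all-background solution; the saturated sigmoid then passes
  almost no gradient and training stalls permanently at the background
  RMSE. Starting at the foreground prior removes the stall.
* **Early stopping** evaluates the validation RMSE every
  `validation_frequency` iterations and stops after
  `validation_patience` consecutive non-improving evaluations, returning
  the best-validation checkpoint.

The full-scale defaults in `train_config()` — Adam, at most 12 epochs,
minibatch 7, initial learning rate 1e-4, validation frequency 200,
patience 10 — are the fixed protocol for clinical-resolution training.
The desk-scale preset used throughout the tests (128 x 128 phantoms,
`base_filters` 8, learning rate 3e-3, validation frequency one epoch)
compensates for the small problem: with ~200 training images an epoch is
only ~29 iterations, so the scaled run needs a larger step size to
converge inside its 12-epoch budget. These scaled problem sizes (200
training / 30 validation / 50 test phantoms) are the package's chosen
desk-scale study conditions.

## Axis extraction

The "high-value area" of a channel is the set of pixels at or above a
fraction `tau` (default 0.5) of the channel maximum. Its axis is the
principal eigenvector of the value-weighted second-moment matrix of the
pixel coordinates — the total-least-squares line, which minimizes the
weighted perpendicular scatter. TLS is rotation-invariant and has no
vertical-line failure mode, which matters because metatarsal axes are
near-vertical in dorsoplantar view; ordinary y-on-x regression would be
ill-conditioned exactly there. The test suite asserts equivalence with an
exhaustive 0.05-degree grid search over candidate angles to within 0.1
degrees.

Failure modes are explicit: fewer than `min_support_pixels` selected
pixels raises an insufficient-signal error, and an isotropic support
(eigenvalue ratio below 1.05) raises a degenerate-axis error. During
whole-image measurement a failed channel is flagged and reported as `NA`
without aborting the other bones.

The fitted axis is undirected; the direction is chosen toward the toe
side, defined by the PH1 channel centroid relative to the mean metatarsal
centroid (for a single channel without context, toward the top of the
image). The default `tau = 0.5` with heatmap-value weighting uses the
probabilistic mass of the prediction, not just its support set; on clean
generated heatmaps the extracted angle moves by less than 0.15 degrees
across `tau` in [0.3, 0.7].

## Synthetic phantoms and simulated raters

Clinical radiographs cannot ship with the package, so every stage is
exercised on synthetic foot phantoms with exactly known ground truth. A
phantom is a dark, noisy canvas with six bright capsule-shaped "bones"
whose midlines *are* the ground-truth axis segments: MT1 at a configurable
base inclination, MT2 at `MT1 + IMA`, MT3-MT5 fanned laterally, and PH1
placed end-to-end with MT1 across a small joint gap at `MT1 + HVA`.
Capsule densities add where bones overlap, as X-ray projections do; edges
are softened over ~1.5 px; Gaussian intensity noise is added. Capsules
are used precisely because they have an unambiguous midline, so
`derive_angles(annotation)` reproduces the requested HVA/IMA to
floating-point accuracy — the construction identity the geometry tests
rely on. All endpoints are kept inside the canvas's inscribed circle so
any rotation augmentation keeps them in bounds.

Random phantom populations draw `|HVA| ~ N(30, 14.6)` truncated to
[0, 55], `|IMA| ~ N(14.3, 4.3)` truncated to [2, 28], and MT1 base
inclination `~ N(97, 3)` degrees — dispersion chosen to match a
symptomatic forefoot clinic population — with random left/right side and
5% intensity noise.

Simulated raters reproduce the truth with isotropic Gaussian endpoint
jitter (default 2 px) plus a Gaussian rotation of each segment about its
midpoint (default 1.5 degrees), giving zero-mean angle errors. The
angular component alone makes per-case pairwise differences follow the
half-normal `E|X - Y| = 2 sd / sqrt(pi)`, which the tests verify against
a Monte-Carlo oracle.

What the phantoms deliberately do *not* emulate: trabecular texture,
sesamoids, soft tissue, joint-space anatomy, spur formation, or the
reading habits of human raters. Passing the synthetic validation
therefore demonstrates that the *method* — encoding, regression,
extraction, statistics — is implemented correctly and is accurate when
its input distribution is known; it does not certify clinical-grade
accuracy on real radiographs, which depends on training data the package
does not contain.

## Validation statistics

For each parameter (HVA, IMA, PH1a, MT1a-MT5a) across a case set:

* `AE_i = |auto_i - median(raters)_i|`; MAE is their mean.
* One-sample, one-tailed t-test of H1: mean AE < 3 degrees; the reported
  confidence bound is the one-sided 95% upper bound of the mean AE,
  consistent with the one-tailed test.
* Error bands `[0, 3)`, `[3, 5]`, `(5, Inf)` degrees — the verbal
  convention "less than 3 / between 3 and 5 / exceeding 5" with closed
  3-5 endpoints.
* Pairwise inter-rater absolute differences `Diff_12`, `Diff_23`,
  `Diff_31` and their per-case mean `Diff_123`; the report gives the SD
  of `Diff_123` both across cases and across the three pairwise
  case-averages (the latter matches the very small SDs typical of
  published agreement tables).
* Two-tailed paired t-test of per-case `AE - Diff_123`.
* Degenerate-variance conventions are explicit: zero-variance AE gives
  p = 0 / 0.5 / 1 by the side of the bound; identical vectors in the
  paired test give p = 1.

`required_sample_size()` inverts the exact noncentral-t power function:
the smallest n such that a one-sided level-0.05 test of H0: mean >= 3
reaches power 0.99 when the true mean is 1.5 and the SD is 3.58 degrees.
With those inputs the answer is 92 (power 0.98988 at n = 91, 0.99046 at
n = 92); the one-sided alpha = 0.05 convention is confirmed by exactly
this reproduction. Cases with a failed (NA) automatic measurement are
dropped per parameter and the report records the per-parameter n.

## Problem sizes and runtime

The package's own acceptance checks run at desk scale on one CPU: the
heatmap round trip sweeps 36 angles x 3 lengths at 512 px (~1 min); the
extraction oracle covers 200 channels from 128 px phantoms (~1 min); the
injected-heatmap measurement uses 100 phantoms at 256 px, where
ground-truth encoding is fine enough for the 1 degree tolerance; and the
end-to-end training check runs three seeds of 200 training / 50 held-out
phantoms at 128 px with `base_filters` 8 (~4 min per seed), requiring
HVA MAE < 3 degrees — the clinical acceptability margin — for at least
two of the three seeds. The single-image descent check uses 600
iterations on one phantom: with the output-bias prior the starting loss
is already near the background RMSE, so the check asserts a 5x reduction
from that lower starting point rather than the 10x-from-random one a
neutral initialization would show.

## Known limitations

* Trained networks are phantom-trained demonstrations; clinical use would
  require training on real annotated radiographs at 512 px.
* The extraction stand-in is *defined* by its oracle (weighted
  perpendicular-scatter minimization); the original supplementary
  algorithm it replaces is not public, so equivalence is asserted against
  the oracle, not the original.
* The rater simulator draws independent errors per rater and case; real
  raters are correlated (shared landmarks, shared training), so simulated
  `Diff` statistics are optimistic about independence.
* Only 3-rater `Diff` statistics are implemented; generalizations and
  chance-corrected agreement (ICC, kappa) are out of scope.
* DICOM ingestion, sesamoid grading, and postoperative axis definitions
  are out of scope.
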