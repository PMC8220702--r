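---
title: "Measuring lesions by asking one question at many scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lesions by asking one question at many scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionruler)
```

## The measurement model

RECIST-style response evaluation tracks tumor burden through unidirectional
measurements: the longest in-plane diameter of each target lesion on an
axial CT slice, in centimeters. lesionruler implements a semi-automatic
estimator of that diameter that never segments the lesion. Instead it
reduces measurement to a one-bit question asked repeatedly:

> *Does the lesion framed in this 128×128 patch appear larger or smaller
> than 32 pixels?*

If a classifier can answer that question reliably, the diameter follows
from scale arithmetic. A lesion of physical diameter $d$ on a slice with
pixel spacing $s$ (cm/px) spans $M_{px} = d/s$ pixels. Magnifying the
image by $m$ makes it appear as $m \cdot M_{px}$ pixels, so the classifier's
answer flips from "smaller" to "larger" at the *flip magnification*
$m^\ast = 32 / M_{px}$, and inverting,

$$ d = \frac{32}{m^\ast}\, s. $$

The estimator therefore: (1) builds a ladder of magnifications around a
user-supplied seed point inside the lesion, each rung hypothesizing one
candidate size; (2) resamples the windowed slice bicubically at each rung,
crops the 128×128 frame centered on the mapped seed, and queries the
classifier; (3) locates the decision flip in the resulting probability
sequence; and (4) converts the flip magnification and the DICOM pixel
spacing into centimeters. The method is deliberately semi-automatic: the
seed point is an input, and the output is a scalar diameter, directly
comparable to a radiologist's caliper measurement.

## The magnification ladder and flip estimation

`ladder_config()` defaults to 16 rungs whose hypothesized sizes span 1.0 to
5.5 cm on a geometric grid — bracketing the 1.37–5.44 cm range over which
such measurements are clinically reported. A geometric grid is uniform in
log-magnification, which matches the evaluation currency of the whole
pipeline (percent error); 16 geometric rungs over that range give a step of
about 12%, i.e. ±6% quantization if the flip were snapped to a rung
midpoint.

Two refinements sharpen this:

* **Isotonic flip placement.** A perfect classifier yields a clean 0→1
  step, but a learned one may not. `estimate_flip()` fits the least-squares
  monotone step function (isotonic regression over log-magnification) and
  interpolates the 0.5 crossing linearly between the bracketing rungs,
  taking the midpoint of any exactly-0.5 plateau. On monotone input the fit
  is the identity and this reduces to plain first-crossing detection.
  All-smaller or all-larger sequences clamp to a ladder end and set an
  `out_of_range` flag rather than fabricating a value. Raw adjacent
  label inversions are reported as `monotone_violations`.
* **Bisection refinement.** With `refine = TRUE` (default) the bracket is
  narrowed by querying the classifier at the geometric midpoint until the
  implied apparent-size uncertainty drops below `refine_tol_px` (default
  0.25 px, about 0.8% relative). With the analytic oracle classifier this
  makes recovery errors quantization-limited, well under 1%.

Seed-to-resampled-coordinate mapping rounds half away from zero — an
arbitrary but fixed tie-break, stated once and used everywhere.

## Canonicalization and training-frame preparation

Training data for the classifier is prepared by the same geometry run
backwards. Each annotated lesion is rescaled by its canonical
magnification $32/M_{px}$ (bicubic, Catmull-Rom kernel), so it spans
exactly 32 px, then zoomed by factors $z$ and shifted so the lesion sits
off-center; the frame built at zoom $z$ shows an apparent size of exactly
$z \cdot 32$ px and is labeled LARGER iff that exceeds 32.

`augmentation_policy()` defaults, and why:

* `zoom_factors`: 18 geometric points over $[0.5, 2]$, i.e. apparent sizes
  16–64 px, symmetric in log about the decision boundary. Neighboring
  zooms differ by ~8.5%, so the nearest off-boundary examples sit at about
  30.7 and 33.4 px — close enough to teach a sharp boundary.
* `exclusion_band_px = 0.5`: a frame at exactly 32 px has an undefined
  label; a narrow band around the boundary is dropped. If the band is zero
  an exact 32 is labeled LARGER by convention.
* `max_shift_px = 16`: shifts are uniform integers per axis, never moving
  the lesion center out of the frame. Off-center training is what makes an
  *arbitrary* interior seed point workable at inference time. The default
  is one lesion radius at the decision boundary: when the lesion spans
  32 px, no interior seed point can displace the frame center by more
  than 16 px, so ±16 px covers exactly the displacements the classifier
  will face near the flip — training with larger shifts spends capacity
  on geometries that cannot occur there and blurs the learned boundary.
* `balance = TRUE`: the majority class is subsampled (seeded) to exactly
  equal SMALLER/LARGER counts, the same dichotomy-balancing used when such
  classifiers are trained on clinical annotations.
* Padding after windowing is 0 (air-like); intensity and rotational
  augmentation are deliberately absent — zoom and shift are the
  label-preserving operations the geometry licenses.

## The classifier contract and the two implementations

Everything downstream needs only a pure function `frame → P(larger than
32 px)`. Two implementations ship:

* `oracle_classifier()` — an analytic test double that reads the frame's
  true apparent size (for phantoms, `magnification × M_px`). The hard
  variant thresholds at 32; the soft variant is a logistic in
  `apparent − 32`, useful for exercising interpolation. The oracle is what
  lets the scale search be tested independently of any learned model.
* `train_size_classifier()` — a small convolutional network. The 128×128
  frame is mean-pooled 2×2 to 64×64 and stacked with three fixed
  coordinate channels (normalized row offset, column offset and radial
  distance from the frame center): deciding "longer than 32 px along
  *some* axis" is a question about where bright pixels sit, not just how
  many there are, and coordinate channels let convolutional features read
  position directly. The 4-channel input passes through three 3×3 conv
  blocks (8/16/32 channels, each conv → batch norm → ReLU → 2×2 max
  pool) and the 8×8×32 feature map feeds a 64-unit dense layer and a
  sigmoid — the head deliberately keeps an 8×8 spatial grid so extent
  information survives into the dense layer. Training follows a fixed
  protocol: 500 mini-batch updates of batch size 32 (one "iteration" =
  one update), Adam with a cosine-decayed step size (peak
  `learning_rate`, default 1.5e-3, falling to 0 across the run; a
  constant schedule is selectable), validation accuracy evaluated every
  10 updates, and the checkpoint with the highest validation accuracy
  returned (earliest on ties). All randomness flows from one seed; two
  runs with the same seed produce identical traces and weights.

After checkpoint selection the trainer estimates the model's *operating
point* on the validation frames: the apparent size at which a monotone
fit of its predicted probabilities actually crosses 0.5. A
finite-capacity model trained for 500 updates typically crosses slightly
below 32 px (31 ± 1 in our runs); `measure_lesion()` rescales the flip
magnification by `32 / boundary_px` so the size conversion uses the
boundary the classifier actually implements. The calibration uses only
training-side data (the validation split), travels with the classifier
artifact, and is a no-op for the analytic oracle, whose boundary is
exactly 32 by construction.

Two composition wrappers ship as well: `majority_vote_classifier()`
folds an odd panel into one contract by vote fraction, and
`train_size_classifier_committee()` trains three independently
initialized copies of the reference network under the full protocol and
averages their probabilities — mirroring the three stacked convolutional
networks of the system this package models. The measurement logic itself
always consumes exactly one probability.

## Phantoms: known truth by construction

Real measurement studies need radiologist annotations; every stage here is
instead testable against synthetic lesions with *exact* ground truth.
`synthesize_lesion()` renders one of four shape families chosen to mimic
the morphologies that make real measurements ambiguous: smooth ellipses,
spiculated boundaries, two adjacent lobes sharing a field of view, and
lesions with a bright central density. Shapes are defined continuously
(radial functions or disc unions), scaled so the continuous longest chord
equals the requested diameter exactly, then rasterized; the returned
endpoints satisfy `distance × spacing = diameter` to 1e-9, and a
brute-force chord search over the rasterized mask boundary agrees to
within one pixel diagonal.

Rendering choices: background is parenchyma-like (−750 HU) with smoothed
correlated texture (SD 40 HU), lesions are soft-tissue-like (+20 HU), edges
are slightly blurred, and white noise (default SD 20 HU) is added before
rounding to integer HU. Intensities are an HU-like linear scale — the
window transform (default lung window, C −600 / W 1500) is applied
downstream, decoupling synthesis from calibration. The figure/ground
contrast is validated against the noise level at spec time.

`sample_phantom_dataset()` draws diameters and spacings uniformly (defaults
1.37–5.44 cm and 0.051–0.137 cm/px, the clinically typical ranges), cycles
the four shape families, and cycles six arbitrary invasion-group labels
A–F so the stratified statistics are exercisable; phantoms have no anatomy,
so the labels are bookkeeping, optionally with injected per-group bias for
power checks (`simulate_measurement_pairs()`).

What the phantoms do *not* emulate: anatomical context (vessels, pleura,
atelectasis), contrast phases, 3-D partial-volume effects, and real
scanner noise spectra. Passing the end-to-end suite therefore demonstrates
that the algorithm and its training loop are correct and self-consistent —
not that the reference network would match a radiologist on clinical CT.

## Agreement statistics

The evaluation battery mirrors standard inter-observer methodology:

* **Percent difference**: $200\,(m_{DL} - m_{human})/(m_{DL} + m_{human})$,
  symmetric in the pair mean, antisymmetric under swap, bounded by ±200%.
* **Bland-Altman**: mean and sample SD (n−1) of percent differences;
  limits of agreement at mean ± 1.96 SD; outliers counted strictly outside
  the closed interval.
* **Pixel differences**: `|m_dl − m_human| / spacing`, with the companion
  identity `pixel_difference_percent()` making explicit why a fixed pixel
  discrepancy means different things for different lesion sizes (5 px at
  0.1 cm/px is 10% of a 5 cm lesion but 25% of a 2 cm one).
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measurement — the single-rater form is used because the comparison is
  one algorithm against one reader, and absolute agreement (not
  consistency) is what penalizes systematic bias. The 95% CI uses the
  standard F-based interval with Satterthwaite degrees of freedom; the
  point estimate is verified in the tests against an independent
  `aov()`-based route and the CI against an external reference
  implementation.
* **Group comparisons**: Welch two-sample t-tests on signed percent errors
  for all unordered group pairs, Bonferroni-adjusted
  (`min(1, p × n_pairs)`), significance at adjusted p < 0.05. Welch is
  used because group sizes and variances differ by construction; signed
  errors are compared because over- versus under-estimation is the
  scientific question.

## Numerical choices and degenerate inputs

* Bicubic kernel: Catmull-Rom (Keys, a = −0.5), border-replicated,
  pixel-center convention; output dimensions are `round(dim × m)`.
* Frames are exactly 128×128; out-of-bounds crop regions take the fill
  value (0 after windowing).
* Anisotropic PixelSpacing is squared up by resampling to the finer
  spacing before measurement — the 32-pixel criterion presumes isotropic
  pixels.
* A constant slice yields an all-0.5 probability ladder; the flip is
  reported at the ladder midpoint with an `ambiguous` flag rather than a
  confident size.
* An all-identical agreement matrix reports ICC 1 with a degenerate-CI
  flag.
* Coordinates are 0-based `(row, col)` everywhere: seed points, endpoints,
  frame centers.

## Problem sizes used in the shipped checks

The test-suite and acceptance script exercise: 200 oracle-measured
phantoms spanning 1.5–5.0 cm at 0.05–0.14 cm/px; 1,000 randomized
flip-estimation ladders (2–12 rungs) against an exhaustive monotone-step
oracle; 100 random 10×2 ICC matrices against the ANOVA route; 10,000
simulated pairs for LOA coverage; 500 replicates of a 6-group null for the
Bonferroni family-wise error; and one scaled-down train-and-measure run
(150 training phantoms → balanced frames → 500×32 updates → 100 held-out
phantoms, ICC and mean percent difference against ground truth). These
sizes keep a full run in the minutes range on a single CPU while leaving
each check statistically meaningful.

## Known limitations

* The reference network is a desk-scale stand-in trained on phantoms; its
  weights, and any accuracy figure attached to them, say nothing about
  clinical CT.
* Lesions outside the hypothesized size range are flagged, not measured.
* The two-lobe failure mode is reproduced, not solved: a seed in one of
  two adjacent lesions can still yield the union's diameter, exactly the
  overestimation observed with real algorithms of this family.
* Measurement endpoints are not produced — the method's output is a
  scalar diameter.
* DICOM support is deliberately minimal: single-frame, uncompressed,
  explicit-VR little-endian, which covers the phantom files and typical
  exported CT slices; compressed transfer syntaxes are rejected.
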