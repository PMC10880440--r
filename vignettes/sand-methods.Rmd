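---
title: "Semi-supervised active-neuron segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised active-neuron segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the science implemented by `sandseg`: what each stage
of the SAND pipeline assumes and computes, which parameters matter and why
their defaults were chosen, what the synthetic scenes do and do not emulate,
and the numerical decisions a maintainer should know about.

## The problem

In two-photon calcium imaging a neuron's activity appears as a transient
brightness increase of its soma, riding on a noisy, slowly varying
background. "Active neuron segmentation" asks for one binary mask per
neuron that was active anywhere in the movie, plus the frames on which it
was active. Fully supervised segmentation networks solve this well but need
every neuron in a training movie annotated. SAND's premise is that ten
labeled frames — a few dozen neuron annotations — carry enough signal if
three sources of leverage are combined: a physics-informed SNR
representation, an ensemble that turns unlabeled frames into soft training
targets, and hyperparameter estimation that never looks at unlabeled
ground truth.

## SNR preprocessing

Calcium transients have a stereotyped asymmetric shape (fast rise, slow
decay). Correlating each pixel's trace with a template of that shape is the
matched filter for it: it maximizes SNR against white noise. The template
is built from the data itself — labeled neurons' SNR traces are scanned for
isolated transients whose peak SNR lies in [5, 8] (strong enough to be
clean, weak enough not to be outliers); snippets are aligned at their
peaks, averaged, truncated where the average falls below 5% of its peak,
peak-normalized and time-reversed. A transient must dominate its whole
snippet window to qualify; secondary bumps riding on larger compound events
would otherwise misalign the average. When no transient falls inside the
band (routine in very low SNR data) the kernel falls back to all detected
transients, with a warning.

The filtered video is then normalized per pixel:
`snr = (filtered − median) / noise`, with `noise = (Q50 − Q25) / 0.6745`,
the lower-sided quartile spread. The lower side is deliberate: transients
are positive-going, so an upper-sided spread would absorb signal into the
noise estimate. The constant 0.6745 makes the estimator consistent for a
Gaussian. Quantiles interpolate linearly between order statistics (R type
7) everywhere in the package. A noise floor of 1e-6 guards degenerate
(dead) pixels. This representation is invariant to per-pixel gain and
offset, which is what makes a threshold like "SNR > 3" transferable across
pixels and recordings.

Activity is defined from this representation: a neuron is active on a frame
when its SNR trace (mean SNR over its footprint) exceeds `activity_thresh`,
default 3 noise units — a conventional ~3-sigma criterion; the prior work
SAND builds on does not restate its exact value, so the package exposes it
as a parameter.

## The U-Net ensemble

Three shallow U-Nets share an encoder layout (3x3 convolutions with 4, 8,
10 channels, each followed by ReLU, dropout and 2x2 max pooling; a
12-channel bottleneck) and differ in decoder width: variant A (8, 6, 6
channels, deepest first), B (10, 8, 6) and C (12, 10, 8), all with
nearest-neighbor upsampling and skip concatenations. Trainable parameter
counts are 5221, 6161 and 7445 — deliberately tiny networks, fast enough
for real-time inference and hard to overfit with ten labeled frames.
Dropout is 0.1 at the first two depths and 0.2 at the deepest. The exact
decoder widths of the original architectures are not published as text;
these were chosen to land at the reported ~5000/~6000/~7500 counts, and the
package enforces the count ordering A < B < C and the < 10,000 bound
rather than exact equality. Inputs are reflection-padded to multiples of 8
(three downsamplings) and outputs cropped back.

Supervised stages minimize `focal + 0.01 * dice`; only the 100:1
focal-to-dice ratio is prescribed, the absolute scale being absorbed by the
learning rate. Focal loss uses the standard form
`mean(−alpha * (1 − p_t)^gamma * log p_t)` with gamma = 2 and alpha = 0.25
(the conventional defaults; alpha scales both classes so that gamma = 0,
alpha = 1 recovers binary cross-entropy exactly). Dice uses a smoothing
constant of 1 pixel so empty frames do not divide 0 by 0. Predictions are
clipped to (1e-7, 1 − 1e-7) inside the losses. No deep-learning framework
is involved: forward and backward passes of the fixed architecture are
implemented directly (RcppArmadillo), with gradients verified against
central finite differences in the test suite; all stochasticity (weight
initialization, dropout, shuffling, augmentation) draws from R's RNG, so a
single `set.seed()` makes entire training runs bit-reproducible.

The schedule is: train all three variants on the labeled frames (200
epochs at full scale); average their probability maps on 1,800 unlabeled
frames, sampled uniformly without replacement and excluding labeled frames,
into soft pseudolabels; continue training variant A on the pseudolabels
with binary cross-entropy (25 epochs, targets kept soft — averaging is the
ensemble's variance reduction, and thresholding would discard its
confidence information); fine-tune variant A on the labeled frames (200
epochs). Adam with learning rate 0.001 and random flips/rotations (the
dihedral group of the square, same transform applied to frame and target)
are used throughout. Batch size defaults to 4 frames: with ten labeled
frames, larger batches would collapse an epoch into a single optimizer
step. Each model's augmentation stream is independent.

## Postprocessing

The probability maps are converted to unique neurons in four steps, each
governed by one hyperparameter. Binarization is strictly greater than
`p_thresh` (mirroring the strict inequalities of the merge criteria).
Components are 8-connected — somas are blobs, and 4-connectivity would
split anti-aliased edges — and must reach `min_area` pixels. Merging takes
the transitive closure, over all frames' components, of the colocalization
relation: center-of-mass distance < `centroid_dist`, or IoU > 0.5, or
consume ratio > 0.75 evaluated with the larger mask consuming the smaller.
The closure is computed exactly by union-find with a lossless spatial
pre-filter (the overlap branches require intersecting bounding boxes; the
distance branch is checked directly), so the result is independent of
component ordering. A merged ROI's final mask keeps pixels present in at
least half of its member components (falling back to the union if that is
empty) — robust to per-frame flicker at the mask boundary; the
consolidation rule is not prescribed by the original description and is
configurable in spirit: it lives in one small function. Finally, ROIs
without a run of at least `min_consecutive` consecutive active frames are
discarded, removing speckle that no calcium transient could produce.

## FLHO

The four hyperparameters are estimated from labeled frames only.

1. For each labeled neuron, the median probability-map value inside its
   mask, over its active labeled frames (median of per-frame in-mask
   medians). Neurons never active on a labeled frame are excluded.
2. The 25th percentile of those medians is the *intermediate* threshold —
   deliberately low, because ten frames rarely catch each neuron at its
   brightest; the median, capped at 0.8, is the *final* `p_thresh`.
3. A grid search over `min_area` and `centroid_dist` (binarizing at the
   intermediate threshold) maximizes frame-level F1 on the labeled frames.
   Each grid point runs extraction and merging; every merged ROI is scored
   by its consolidated final mask on the frames where it is active. Scoring
   final masks rather than raw per-frame components matters: a
   `centroid_dist` large enough to chain two different neurons across
   different frames still produces correct per-frame components, and only
   the final-mask score exposes the damage. F1 counts are pooled across
   frames (stable when single frames hold few neurons). Ties prefer the
   smaller `centroid_dist`, then the larger `min_area` — conservative
   merging and noise rejection.
4. With `p_thresh` and `min_area` fixed, the longest consecutive run of
   frames with a component colocalized with each neuron's mask is computed
   over *all* frames (probability maps only — no unlabeled ground truth).
   `min_consecutive` is the second smallest nonzero run length — the
   minimum is occasionally an outlier — capped at 8 frames, with the
   smallest value as fallback when only one neuron was detected.

The default grid is 30:10:150 px for `min_area` (appropriate at ~1 um/px)
scaled by `(soma_radius / 6)^2` for other magnifications, and 2:1:10 px for
`centroid_dist`.

## Synthetic scenes

The generator renders `baseline + neuropil + sum_i trace_i * footprint_i +
noise`. Footprints are rasterized random ellipses (semi-axes 3–5 px in a
64x64 field); placement enforces the pairwise-overlap cap (5% of the
smaller area by default) on 1-px-dilated footprints, so somas are separated
by background except for deliberate overlaps — matching both cortical
anatomy (neuropil separates most somas) and the merging rule's operating
assumption that heavily overlapping components are the same neuron. Spikes
are Bernoulli per frame (0.008/frame by default, a sparse-firing regime:
~8 events per 1000 frames per neuron); each spike contributes
`(1 − e^(−t/rise)) * e^(−t/decay)` (rise 2, decay 8 frames) scaled so its
peak equals an amplitude drawn from the configured range. Neuropil is a
smooth random field times a slow sinusoid, exercising the median/noise
normalization. Per-neuron randomness is sub-seeded by neuron index, so a
neuron's spike train does not depend on the placement retries of others.

Two presets define the benchmark regimes: the easy scene (amplitudes 5–7 at
noise sigma 1) lands at a median post-filter peak SNR near 10; the hard
scene (amplitudes 1.4–2.0) near 5. These match the regimes where the
method is reported to work well and to degrade, respectively. The scenes do
**not** emulate motion artifacts (registration is assumed), dendrites and
axons, one-photon background contamination, or correlated noise — so
passing tests demonstrate correctness of the pipeline's logic and its
behavior under controlled SNR, not performance on real recordings.

## Problem sizes and reference experiments

The package's reference experiments (test suite and `scripts/acceptance.R`)
use 64x64x1000 scenes with 20 neurons, 10 labeled frames, a reduced
50/10/50-epoch schedule and 200 pseudolabel frames — a desk-scale profile
chosen so a full experiment fits in about a minute on one CPU while
preserving every structural property of the full 200/25/200 x 1800-frame
schedule. On the easy scene this recovers neurons at F1 ≈ 0.83–0.95
(median ≥ 0.8 over seeds); accuracy is flat across intermediate-percentile
choices {15, 20, 25, 30}; and on the hard scene SAND's median F1 exceeds a
single-model baseline tuned by a full four-parameter grid search on the
same labeled frames. Those numbers are computed, not quoted: the
acceptance script recomputes them from scratch at every run.

## Numerical choices, degenerate inputs, limitations

- Coordinates and frame indices are 1-based throughout (R convention),
  including all JSON output.
- Quantiles: linear interpolation (type 7) everywhere; medians of even
  counts interpolate.
- Convolution boundaries: temporal filtering uses mirror reflection;
  spatial padding for the U-Net reflects edges; both avoid edge dimming
  that would bias frame selection or masks.
- The convex-hull mask quality rasterizes the hull over pixel centers
  (a pixel counts when its center is inside or on the hull polygon);
  masks with fewer than three non-collinear pixels score 1.
- Empty-mask operations raise typed conditions (`sandseg_empty_mask`);
  IoU of two empty masks returns 0 with a warning.
- Mask matching is greedy by descending IoU. It can differ from the
  optimal assignment in rare geometries; the test suite bounds the
  discrepancy (≥ 95% agreement with exact maximum matching on random
  instances).
- Known low-SNR pathology: a barely trained network can output a
  probability plateau inside somas. FLHO's median then coincides with the
  plateau value and the strict `>` binarization discards everything —
  observed on one hard-scene seed. This is a property of the published
  procedure, surfaced honestly rather than patched; the practical remedy
  is more labeled frames or a longer schedule.
- The pseudolabel stage assumes the ensemble is better than its members
  on unlabeled frames (variance reduction). At very low SNR individual
  members can be so weak that pseudolabels dilute rather than denoise;
  the hard-scene experiments show exactly this failure mode on some seeds.
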