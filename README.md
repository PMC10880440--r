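# sandseg

Semi-supervised segmentation of active neurons in two-photon calcium-imaging
videos from a handful of labeled frames.

Two-photon calcium imaging records neural activity as transient brightness
increases of neuron somas. Supervised segmentation networks detect these
active neurons accurately, but need every neuron in a training video labeled
by hand — thousands of masks. `sandseg` implements **SAND**
(Semi-supervised Active Neuron Detection), which reaches comparable accuracy
from roughly ten labeled frames by combining:

1. **SNR preprocessing** — every pixel trace is correlated with a matched
   calcium-transient template (built from labeled transients with peak SNR
   between 5 and 8, peak-aligned, averaged, time-reversed), then converted
   to SNR units: `snr = (filtered − median) / noise`, with a per-pixel
   temporal median and a quantile-based noise estimate
   `(Q50 − Q25) / 0.6745`.
2. **A pseudolabel ensemble** — three shallow U-Nets (shared encoder layout,
   decoder widths giving ≈5200 / ≈6200 / ≈7400 trainable parameters, dropout
   0.1/0.1/0.2 by depth) are trained on the labeled frames with a
   focal + dice loss at a 100:1 weighting. Their probability maps on 1,800
   unlabeled frames are averaged into soft pseudolabels; the smallest
   U-Net continues training on them with binary cross-entropy (25 epochs)
   and is fine-tuned on the labeled frames again (Adam, learning rate 0.001,
   flip/rotation augmentation throughout, 200/25/200 epochs at full scale).
3. **Postprocessing** — probability maps are thresholded (`p_thresh`,
   strictly greater), 8-connected components below `min_area` are removed,
   components are merged across frames when colocalized (center-of-mass
   distance < `centroid_dist`, IoU > 0.5, or consume ratio > 0.75; the full
   transitive closure), and merged ROIs without a run of `min_consecutive`
   consecutive active frames are discarded.
4. **FLHO** (Few Label Hyperparameter Optimization) — estimates all four
   postprocessing hyperparameters from the labeled frames alone: `p_thresh`
   from the distribution of per-neuron median in-mask probabilities (25th
   percentile for intermediate steps, the median — capped at 0.8 — as the
   final value), `min_area`/`centroid_dist` by a grid search maximizing
   frame-level F1 on labeled frames, and `min_consecutive` as the
   second-smallest per-neuron maximum consecutive-detection count, capped
   at 8 frames.

A seeded synthetic-scene generator (elliptical somas, Bernoulli spikes,
double-exponential transients, smooth neuropil, Gaussian noise) provides
ground truth for development and validation, and evaluation utilities cover
greedy IoU mask matching, recall/precision/F1, neuron peak SNR, and the
convex-hull mask-quality ratio.

## Worked example

```r
library(sandseg)

# A 64x64x1000 scene with 20 neurons at median peak SNR ~ 10.
scene  <- generate_scene(easy_scene_config(seed = 11))

# Matched-filter + SNR preprocessing, using the labeled neurons' transients.
kernel <- build_kernel_from_labels(scene$video, scene$scene$footprints)
snr    <- snr_normalize(temporal_filter(scene$video, kernel))

# Label the neurons active on 10 random frames (the only supervision used).
set.seed(1101)
frames  <- select_training_frames(snr, 10)
labeled <- make_labeled_set(scene$scene, snr, frames)

# Staged semi-supervised training (desk-scale 50/10/50 schedule).
fit  <- run_sand_training(snr, labeled, desk_train_config(seed = 1101))
prob <- predict(fit$model, snr)

# Hyperparameters from the labeled frames alone, then postprocessing.
hp      <- run_flho(snr, prob, labeled, grid = grid_spec(soma_radius = 4))
neurons <- postprocess(prob, hp)

unlist(hp[c("p_thresh", "min_area", "centroid_dist", "min_consecutive")])
#>        p_thresh        min_area   centroid_dist min_consecutive
#>            0.80              13               2               8

metrics <- precision_recall_f1(match_masks(neurons, scene$scene$footprints))
str(metrics)
#> List of 3
#>  $ recall   : num 0.75
#>  $ precision: num 0.938
#>  $ f1       : num 0.833
```

FLHO capped `p_thresh` at 0.8 (the trained network is confident inside
somas), chose an area cutoff of 13 px against speckle, a conservative 2 px
merge radius, and the 8-frame cap on `min_consecutive`; 16 of the 20
ground-truth somas were recovered at IoU ≥ 0.5 with only one false
positive (F1 = 0.83 from 10 labeled frames).

`run_pipeline()` wraps all stages (including artifact persistence) and
`inst/cli/sand` exposes them as shell subcommands
(`simulate`, `preprocess`, `run`, `postprocess`, `evaluate`).

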