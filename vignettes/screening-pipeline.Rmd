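---
title: "A weakly supervised screening pipeline for urine liquid-based cytology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A weakly supervised screening pipeline for urine liquid-based cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Urine cytology screens for urothelial carcinoma: a cytoscreener scans a
liquid-based cytology (LBC) slide for sparse neoplastic urothelial cells --
enlarged, hyperchromatic nuclei with a high nuclear/cytoplasmic ratio --
among thousands of benign cells, debris and crystals. Digitised as a
whole-slide image (WSI), a slide is gigapixel-scale while the diagnostic
evidence may occupy a tiny fraction of it. `uroscreen` implements the
standard tile-based answer to this: classify fixed-size tiles at a working
magnification, assemble per-tile probabilities into a heatmap, and report
the slide-level probability as the maximum over tiles.

The slide-level label set follows cytodiagnostic practice: reporting
classes I-II are negative, III-V (atypical through high-grade urothelial
carcinoma) are neoplastic. Annotated neoplastic cells carry one of three
labels (atypical / LGUC / HGUC cell); all three are grouped into a single
neoplastic training label, so the per-label distinction is metadata only.

## Pipeline

1. **Tissue masking.** Otsu's threshold on a grayscale thumbnail (max
   dimension 2048 px) marks cells: foreground is every pixel *strictly
   below* the threshold, because stained objects are darker than the bright
   LBC background. Ties in the between-class variance are broken toward the
   lowest threshold. A single-valued histogram (blank slide) gives an empty
   mask with a warning rather than an error.
2. **Tile lattice.** Tiles of `tile_size` (default 1024 px) at working
   magnification x10 are anchored on a stride lattice (default 512 px, half
   the tile). Scans are nominally x20, so a tile maps to a level-0 window
   twice its side, which is block-averaged down (factor 2). Coordinates are
   0-based, half-open, level-0 -- the interoperable frame. Partial
   rightmost/bottom lattice positions are kept and padded white (255):
   marginal cells must stay screenable. An anchor is retained when the
   tissue fraction under its footprint is at least `min_tissue_fraction`
   (default 0.05; LBC spreads are sparse, and the value is configurable).
3. **Tile positivity (fully supervised route).** A tile is positive when
   at least one annotation polygon intersects its rectangle with *positive
   area* -- the operational reading of "an annotated cell is visible
   anywhere inside the tile". Centroid containment would miss straddling
   cells; boundary contact alone does not count.
4. **Training** (below).
5. **Inference.** One forward pass per retained anchor; the heatmap stores
   one probability per lattice cell, `NA` for non-tissue cells, so "no
   cells here" is distinguishable from "confidently negative". The slide
   score is the maximum over evaluated cells; overlapping tiles are not
   blended. Overlays colour the heatmap with the jet map (blue = low,
   red = high).

## Training regimes

**Fully supervised (FS).** Batches are exactly class-balanced and
interleaved (P,N,P,N,...): positives drawn uniformly with replacement from
tiles of annotated neoplastic slides that pass the positivity rule,
negatives drawn from negative slides. After every epoch, full
sliding-window inference runs on all negative training slides and the
negative sampling weights are refreshed to `w_i ∝ ε + p_i` with `ε = 0.01`
-- false-positive hard mining. The additive floor is our choice (the
source method states only "more likely to be sampled"); it keeps
never-predicted regions in circulation. The FS epoch length is
`ceiling(P / (batch_size/2))` steps for `P` qualifying positive anchors
(minimum 1) -- also a stated substitute, since no epoch length is published.
A neoplastic slide without annotations is a configuration error on this
route (it is fine on the weakly supervised route).

**Weakly supervised (WS).** Only slide labels are used. Each epoch visits
every training slide once in a seeded random permutation (the published
"oversampling so the model trains on tiles from all WSIs each epoch" is
interpreted as this cycling rule). Per slide: sliding-window inference,
selection of the `k = 8` highest-probability tiles (ties broken in
row-major anchor order), and a push of those tiles into a fixed-capacity
buffer with the slide's binary label. When the buffer reaches `N = 256`
tiles it is shuffled, consumed in gradient batches of 32, and cleared; it
persists across epoch boundaries. On negative slides the top-k selection
is hard negative mining; on neoplastic slides it concentrates training on
the tiles most likely to carry the sparse signal -- the multiple-instance
assumption that at least one tile of a neoplastic slide is positive.

**FS+WS.** The combined mode runs FS to convergence, then WS from the
FS-best checkpoint. The source lists the two methods jointly without an
explicit schedule; sequential-with-checkpoint-handoff is our design choice,
and the WS phase restarts the epoch counter (and hence the learning-rate
schedule and early-stopping state).

**Optimisation.** Adam (beta1 = 0.9, beta2 = 0.999), binary cross-entropy,
learning rate 0.001 decayed by 0.95 every 2 epochs
(`lr = 0.001 * 0.95^floor(epoch/2)`). Early stopping tracks a validation
loss with patience 10 (strict improvement, min-delta 0) and the final model
is the validation argmin. The validation loss is the *slide-level* binary
cross-entropy of max-aggregated scores: the published method monitors
"validation loss" without defining its level, and the slide level both
matches how the model is reported and works for unannotated validation
negatives. Photometric augmentation (brightness offset, saturation scale,
contrast scale, each uniform in a configured range, output clipped to
[0, 255]) is applied to FS batches; the WS route trains on unaugmented
tiles -- whether the original work augmented WS batches is unstated, and
leaving WS tiles exactly as inference sees them keeps the mined top-k
consistent with the tiles actually trained on.

**Partial fine-tuning.** The backbone contract partitions parameters into
normalization-affine, final-classifier and other; partial mode updates only
the first two groups and leaves everything else bit-identical. The built-in
test backbone is a deliberately small CNN (two 3x3 conv blocks, per-channel
*instance* normalization with affine gamma/beta, global average pooling, a
1-logit sigmoid head) implemented in base R. Instance rather than batch
normalization is a numerical choice: inference becomes independent of batch
composition (the batched-equals-unbatched property holds to 1e-6), at the
cost that a constant-intensity tile is normalized to featurelessness --
discrimination rests on texture and shape, which is what the screening task
needs anyway. Any backbone exposing the same contract
(`predict_tiles`, `train_step`, `parameter_groups`, `get_parameters`)
can be plugged in; input size is a configuration value.

## Evaluation

ROC curves sweep the threshold over all distinct scores with sentinels
above the maximum and at 0; a positive call is `score >= threshold` (the
boundary is stated explicitly because a 0.0-to-1.0 sweep leaves it open).
AUC is the trapezoidal integral, which equals Mann-Whitney pair counting
with ties at 1/2 -- the suite checks this identity to 1e-12. Accuracy,
sensitivity and specificity default to threshold 0.5; the published
operating point is unstated, so the threshold is exposed. Confidence
intervals are percentile bootstrap over slide-level resamples (1000
iterations by default); the interval type is likewise unstated in the
source, and the percentile method is the simplest defensible default.
Single-class resamples, on which AUC is undefined, are discarded and
redrawn. Test splits come in two designs: equal balance (1:1
negative:neoplastic) and clinical balance (10:1 by default, reflecting
screening prevalence); optional per-class quotas over classes I-V are
honoured exactly, and shortfalls fail with the deficient class named.

## The synthetic world

Clinical slides are unavailable, so the package carries a generator whose
defaults state the world the tests run in. A 4096 px square canvas (a
desk-scale stand-in for a gigapixel scan, declared as an x20 single-level
TIFF so the x20-to-x10 resampling path is exercised) holds ~2000 benign
cells, 40 debris fragments and 15 crystals on a bright (235) background.
Benign cells have nuclear radii of 5-9 px with ample cytoplasm; neoplastic
cells, drawn only on neoplastic slides in 3 sparse clusters of 4-10 cells,
have radii of 14-22 px, a chromatin tone darkened by 70 intensity steps,
higher eccentricity and scant cytoplasm (high N/C ratio). Every neoplastic
cell gets exactly one enclosing annotation polygon; negative slides have
empty annotation sets. Neoplastic objects cover well under 5% of the
canvas -- the sparse-signal premise the weakly supervised route relies on.
The acceptance cohort uses the same world at 1024 px with object counts
scaled by canvas area (125 cells, 2 clusters, 3 debris, 2 crystals).

Two generator choices deserve a note. Cytoplasm is drawn at a clearly
stained tone (gray ~165 against the 235 background): with near-background
cytoplasm, Otsu's single threshold lands between nuclei and everything
else, which is also what happens on understained real slides; the
calibration mirrors adequately stained LBC preparations and makes the
tissue mask mean "cells", not "nuclei". And per-slide seeds are
`cohort seed + slide index`, so any slide can be regenerated in isolation.

What the generator does *not* emulate: Papanicolaou colour fidelity,
out-of-focus planes and z-stacks, scanner artefacts and compression, the
continuum of borderline atypia, and overlapping syncytial fragments thicker
than a few cells. A green end-to-end test therefore establishes that the
pipeline's machinery -- masking, tiling, mining, aggregation, evaluation --
recovers a sparse, morphologically distinct signal; it does not establish
clinical performance. The published headline numbers (AUC 0.984-0.990)
belong to a proprietary 750-slide test set and are explicitly not
reproduction targets.

One measured caveat: an *untrained* random backbone already ranks slides
well above chance on this world (AUC ~0.9 in our runs), because random
convolutional features correlate with chromatin darkness and
max-aggregation amplifies any such correlation. The end-to-end acceptance
check therefore asserts the trained AUC >= 0.9 and that training does not
degrade the untrained baseline, rather than asserting the untrained model
sits at exactly 0.5.

## Numerical and degenerate-input choices

* Otsu on an empty or single-valued histogram: error at the operation
  level; `detect_tissue` converts it to an empty mask with a warning.
* Tile reads fully outside the slide: error; partially outside: white
  padding.
* Probabilities are clipped to [1e-15, 1-1e-15] in every cross-entropy.
* An all-sentinel heatmap scores 0 with a warning (a blank slide is
  negative, loudly).
* `select_hard_tiles` with fewer than k anchors returns all of them; an
  empty grid is skipped with a warning during WS epochs.
* Degenerate (zero-area) annotation polygons are skipped with a warning by
  the positivity rule.
* All randomness flows from explicit seeds: the run seed drives epoch
  permutations and sampling; synthetic slides are pure functions of their
  config.

## Limitations

* The slide reader handles uncompressed single-level TIFF (its own writer's
  format) only; pyramidal SVS/JPEG2000 files need an external conversion
  step. This matches the package's role as a testable reference
  implementation rather than a scanner-facing deployment.
* The built-in backbone is intentionally tiny; the published architectures
  (EfficientNetB1 and friends) and their pretrained weights are out of
  scope, as is the uterine-cervix weight initialisation (`init =
  "checkpoint"` accepts any compatible file).
* Bootstrap CIs are percentile, not BCa; with small slide counts the
  intervals are known to be slightly anti-conservative.
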