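# uroscreen

Tile-based screening of urothelial carcinoma in whole-slide images (WSIs)
of urine liquid-based cytology (LBC) specimens.

Urine cytology looks for sparse neoplastic urothelial cells — nuclear
enlargement, hyperchromasia, high nuclear/cytoplasmic (N/C) ratio — among
thousands of benign cells, debris and crystals on a gigapixel slide. This
package implements the standard deep-learning answer as a fully testable R
pipeline:

* **Tissue masking** — Otsu's threshold on a grayscale thumbnail; foreground
  is everything strictly darker than the threshold.
* **Tiling** — tiles of side `t` (default 1024 px) at working magnification
  ×10 on a stride-`t/2` lattice in level-0 coordinates, with ×20→×10
  block-average resampling and white edge padding.
* **Fully supervised training (FS)** — class-balanced interleaved batches
  (positives = tiles showing ≥ 1 annotated cell, by positive-area
  polygon–rectangle intersection) with end-of-epoch false-positive hard
  mining of negative slides: sampling weight *w ∝ ε + p*.
* **Weakly supervised training (WS)** — multiple-instance learning from
  slide labels only: per slide visit, the *k* = 8 highest-probability tiles
  are pushed with the slide's label into a capacity-*N* = 256 buffer that is
  shuffled, consumed in batches of 32 and cleared whenever it fills.
* **Inference** — sliding-window heatmap (one probability per anchor, `NA`
  sentinel off-tissue), slide score = max over tiles, jet-colormap overlays.
* **Evaluation** — ROC/AUC (trapezoid ≡ Mann–Whitney), log-loss, accuracy /
  sensitivity / specificity, percentile-bootstrap 95% CIs (1000 iterations),
  and equal-balance (1:1) / clinical-balance (10:1) test-split builders with
  per-class quotas over cytology classes I–V (I–II negative, III–V
  neoplastic).
* **Synthetic slides** — a seed-reproducible generator of LBC-like slides
  with paired polygon annotations and manifests, so every stage above is
  testable without clinical data.

Optimisation follows the published operating point: Adam (β₁ = 0.9,
β₂ = 0.999), binary cross-entropy, learning rate 0.001 with ×0.95 decay
every 2 epochs (`lr(e) = 0.001·0.95^⌊e/2⌋`), early stopping on slide-level
validation loss with patience 10, and optional partial fine-tuning that
updates only normalization-affine parameters and the final classifier. The
backbone is pluggable; the built-in test backbone is a small pure-R CNN.

## Worked example

Generate a small synthetic cohort, score each slide with the built-in
reference scorer, and evaluate at an operating threshold of 0.6:

```r
library(uroscreen)

cfg <- synthetic_slide_config(width = 512, height = 512, n_normal_cells = 32,
                              n_neoplastic_clusters = 1, cells_per_cluster = c(4, 8),
                              n_debris = 2, n_crystals = 1)
co     <- generate_cohort(6, 6, cfg, seed = 7, split = "test")
cohort <- cohort_from_bundles(co$bundles)

scorer <- intensity_scorer()   # frozen reference model (no training)
preds <- data.frame(
  slide_id = cohort$records$slide_id,
  score = vapply(cohort$records$slide_id, function(sid)
    predict_slide(cohort$slides[[sid]], scorer, tile_size = 128, stride = 64)$score,
    numeric(1)))

evaluate_predictions(preds, cohort$records, threshold = 0.6,
                     n_bootstrap = 500, seed = 1)
```

```
Slide-level metrics (n = 12, threshold 0.60, 500 bootstrap iterations)
  roc_auc      1.000 [1.000-1.000]
  log_loss     0.454 [0.275-0.645]
  accuracy     0.917 [0.750-1.000]
  sensitivity  1.000 [1.000-1.000]
  specificity  0.833 [0.500-1.000]
```

Each line is a point estimate with a percentile-bootstrap 95% CI over
slide-level resamples. The max-darkness reference scorer separates the six
neoplastic slides (scores 0.76–0.96, driven by their hyperchromatic
clusters) from the six negatives (0.46–0.63) perfectly by rank (AUC 1.0);
at the 0.6 threshold one negative slide with dark debris is still called
positive, which is exactly the false-positive mode the FS hard-mining loop
exists to suppress. Training a real backbone end to end is one call:

```r
config <- train_config(tile_size = 128, stride = 64, mode = "WS",
                       max_epochs = 15, seed = 42)
fit <- train_model(cohort, tiny_cnn(128, seed = 42), config)
```

On the acceptance cohort (30 train / 10 validation / 40 test synthetic
slides at 1024², ×20 declared), this lifts held-out slide-level AUC to 1.0
in about 5 minutes on one CPU (see `test-acceptance.R`, criterion 6).

## Command line

```sh
inst/cli/uroscreen simulate --n-negative 5 --n-neoplastic 5 --out cohort --seed 1
inst/cli/uroscreen split    --manifest cohort/manifest.csv --design clinical --n-neoplastic 2 --ratio 10
inst/cli/uroscreen train    --manifest cohort/manifest.csv --base-dir cohort --mode ws --out run
inst/cli/uroscreen predict  --manifest cohort/manifest.csv --base-dir cohort --checkpoint run/checkpoint.rds --out preds
inst/cli/uroscreen evaluate --predictions preds/predictions.csv --manifest cohort/manifest.csv --out report.json
```

## Scope

Single-level uncompressed TIFF (plus in-memory arrays) only — no
SVS/JPEG2000 codecs; no stain normalisation; no annotation UI; the
published CNN architectures and pretrained weights are out of scope (the
backbone contract accepts any drop-in). See
`vignettes/screening-pipeline.Rmd` for the full methods account.
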