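Package: uroscreen
Title: Weakly Supervised Screening of Urothelial Carcinoma in Urine
    Liquid-Based Cytology Whole-Slide Images
Version: 0.1.0
Authors@R: person("Urine LBC Screening Contributors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tile-based screening pipeline for whole-slide images of urine
    liquid-based cytology specimens. Provides Otsu tissue masking, stride-lattice
    tile extraction with magnification resampling, fully supervised training with
    false-positive hard mining, weakly supervised multiple-instance training with
    per-slide top-k tile selection, sliding-window probability heatmaps with
    max-probability slide scoring, ROC/bootstrap evaluation with equal-balance and
    clinical-balance test-split builders, and a seed-reproducible synthetic slide
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
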