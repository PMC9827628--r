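Package: antcaste
Title: Caste-Comparative Quantification of Ant Olfaction and Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for caste-comparison studies of ant
    olfaction and social behavior. Implements electroantennogram (EAG)
    quality gating and solvent-interpolation normalization, odor-panel
    statistics (Welch tests with two-stage step-up FDR, solvent-relative
    response classification, Fisher's exact test on response signs,
    Kendall tau-b rank concordance with per-pair labels and per-chemical-class
    discordance, four-parameter logistic and hormetic dose-response fits),
    identity-preserving multi-animal centroid tracking from binarized arena
    video or detection streams, trail-following event detection and occupancy
    density maps in calibrated arena coordinates, and frame-wise binary
    aggression scoring with duration, time-course and severe-outcome tests.
    Includes seeded synthetic-data generators emulating each assay so the
    whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
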