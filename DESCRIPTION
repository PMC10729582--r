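Package: microvam
Title: Microglia Morphometrics, Vascular Association and Barrier Leakage
    from Multi-Channel Confocal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies microglial phenotypes in multi-channel fluorescence
    microscopy of brain tissue, as used in studies of hypertensive cerebral
    small vessel disease. Provides self-tuned multi-scale Frangi vessel
    enhancement with hysteresis segmentation, threshold- and size-filter
    based soma and immunoglobulin-G leakage quantification, skeleton-based
    single-cell morphometrics with a ramification (solidity) index,
    classification of vascular-associated microglia, Ward-linkage clustering
    with UMAP embedding of morphology features, the accompanying statistical
    layer (Welch t, two-way ANOVA with Holm-Sidak post hoc, Spearman
    matrices, 2^-ddCt relative quantification), and a synthetic confocal
    field-of-view generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    uwot,
    mclust,
    car,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
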