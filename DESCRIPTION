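Package: adipoquant
Title: Adipocyte Histology Phenotyping from Tile Triage to Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies adipocyte morphology from H&E histology. Whole-slide
    rasters are cut into calibrated tiles, triaged by a three-class
    convolutional classifier, segmented by a U-Net into per-pixel adipocyte
    probability maps, and reduced to QC-filtered cell areas (microns squared)
    and per-sample phenotypes (mean, SD, count of cell areas). Downstream
    statistics cover rank inverse normal transformation, per-cohort linear
    models, fixed- and random-effects (DerSimonian-Laird) meta-analysis with
    heterogeneity, Hardy-Weinberg exact tests, and weighted genetic risk
    scores. A synthetic-data module generates adipose-like tiles with exact
    ground-truth masks, cohort phenotype tables with planted effects, and
    genotype dosages, so the whole pipeline is testable without study data.
    Includes a compact built-in convolutional network engine (RcppArmadillo)
    with SGD/Nesterov and Adam optimizers and a dice + binary cross-entropy
    loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
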