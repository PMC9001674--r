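Package: isochron
Title: Fate Heterogeneity Analysis of Isochronic Cortical Neuron Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of simultaneously-born (isochronic)
    cortical neuron cohorts labelled by FlashTag pulse and chronic BrdU
    birthdating.  Provides intensity gating of directly progenitor-born
    neurons, normalized radial-position and laminar-dispersion statistics,
    single-cell RNA-seq quality control and normalization, a
    permutation-based PC1 variance-explained statistic of within-condition
    molecular heterogeneity, shared-nearest-neighbor community clustering
    with birthdate composition and marker-positive fractions, and a
    synthetic-data generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    Seurat,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
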