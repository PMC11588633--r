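Package: pancradiomics
Title: Radiomic Analysis of Pancreatic Tumor Heterogeneity Across Subregions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies inter-tumor heterogeneity of pancreatic ductal
    adenocarcinoma (PDAC) across pancreatic subregions from contrast-enhanced
    CT volumes. Provides intensity normalization, proportional partition of a
    pancreas mask into head/body/tail, fixed-bin-count discretization, five
    grey-level texture-matrix families (co-occurrence, run length, size zone,
    dependence, neighbourhood grey-tone difference) with named scalar features,
    first-order and 2D/3D shape features, a bin/kernel/angle parameter-grid
    orchestrator, Welch t-test feature screening with Manhattan-plot export, a
    seven-classifier bank with recursive feature elimination capped at five
    features, ROC/AUC evaluation, and a synthetic 3D phantom generator that
    emulates the head versus body/tail class contrasts so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    MASS,
    e1071,
    class,
    ranger,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
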