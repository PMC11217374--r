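Package: synaptometry
Title: Quantitative Synaptic Connectivity from Volume Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying synaptic connectivity in volume electron
    microscopy (FIB-SEM) stacks of brain neuropil. Segments synaptic
    junctions in 3D by Gaussian pre-filtering, gray-level thresholding and
    connected-component labeling; counts them with an unbiased
    three-dimensional counting frame (three acceptance and three extended
    exclusion planes); links junctions to traced fiber skeletons; and
    computes volumetric synapse densities, asymmetric/symmetric synapse
    proportions, linear synapse densities on dendritic spines and shafts,
    fiber-class length densities in meters per cubic millimeter,
    multi-contact and bouton-shape statistics, all with tissue-shrinkage
    correction. Includes seeded generators of phantom image stacks and
    fiber networks with known ground truth, nonparametric group
    comparisons (Kruskal-Wallis with Bonferroni-corrected pairwise tests,
    Mann-Whitney U, chi-square), and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    yaml,
    tiff,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
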