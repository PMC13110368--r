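Package: primquant
Title: Quantitative Morphometrics of the Zebrafish Lateral Line Primordium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, segmentation and statistics for size and composition
    of the zebrafish posterior lateral line primordium (pLLP). Provides a
    synthetic generator of membrane-labeled 3D primordium stacks with exact
    per-cell ground truth, moment-ellipse registration of stacks, single-cell
    3D segmentation by h-minima marker-controlled watershed with robust
    outlier removal, morphometric readouts (cell count, volume, shape
    descriptors, rosette detection, neuromast deposition, stained area),
    fluorescence intensity quantification (reporter means, positive-cell
    counts, line profiles, EdU fractions), and the accompanying statistical
    layer (delta-delta-Ct fold changes, exact and approximate Mann-Whitney
    tests, effect sizes, group summaries, Wilson proportion intervals),
    orchestrated by a reproducible cohort pipeline.
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
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
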