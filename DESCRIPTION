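Package: fcnetclass
Title: Network-Measure Biomarker Discovery from Resting-State Functional
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for data-driven discovery of network biomarkers from
    resting-state functional imaging time series. Voxel time series are
    spectrally prewhitened, grouped into spatially contiguous regions by
    constrained Ward agglomerative clustering of correlation distances,
    and summarised as weighted and density-thresholded binary region graphs
    from which node, pair and global graph-theoretic measures are computed.
    Subjects are classified with support vector machines inside a nested
    (double) cross-validation scheme with single-feature screening and
    sequential forward selection, and the stability of selected features is
    assessed against an exact binomial selection-frequency null. A synthetic
    cohort generator with planted group differences in region coupling makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    e1071,
    igraph,
    MASS,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    oro.nifti,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
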