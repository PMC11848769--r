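Package: wingmorph
Title: Landmark and Outline Geometric Morphometrics for Insect Wing
    Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Dual geometric-morphometric pipelines for species
    identification from insect wings: a landmark-based pipeline
    (generalized Procrustes analysis, centroid size, Procrustes ANOVA
    repeatability, allometry) and an outline-based pipeline for wing
    cells (arc-length resampling, elliptic Fourier analysis with
    first-harmonic normalization, perimeter size variable). Both feed a
    shared statistical stack of shape PCA, canonical discriminant
    analysis, pairwise Mahalanobis distances with permutation tests and
    Bonferroni correction, and chance-adjusted leave-one-out
    classification. Includes a synthetic multi-species wing-data
    generator, TPS/CSV readers and writers, report-table export, and
    nucleotide composition summaries for DNA barcodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
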