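Package: morphoscreen
Title: Robust Screening Analytics for High-Content Morphological Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for image-based drug evaluation assays: curation and
    vehicle-control normalization of Cell Painting well profiles,
    correlation-distance profiling with complete-linkage clustering and PCA
    dose trajectories, per-well morphological-uniformity scores, a modified
    robust Z-prime feature-disruption statistic with genotype-dependency
    adjustment, nuclear:cytoplasmic localization analysis with cell-contact
    filtering and 2-MAD well-outlier removal, and 2D/spheroid growth
    quantification from logistic fits with robust time-point trimming. A
    synthetic-data module generates per-cell tables, block-correlated feature
    matrices with planted genotype-dependent effects, and logistic growth
    tracks with known ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
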