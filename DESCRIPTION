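Package: facegwas
Title: Global-to-Local Multivariate GWAS of 3D Facial Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for multivariate genome-wide
    association studies of dense 3D facial quasi-landmark data. Implements
    generalized Procrustes superimposition, shape symmetrization,
    Mahalanobis outlier QC, covariate adjustment, data-driven global-to-local
    hierarchical segmentation of the landmark set, per-segment principal
    component phenotyping with Horn's parallel analysis, canonical
    correlation genome scans with Rao's F significance, Li-Ji effective
    numbers of tests, greedy locus clumping, five cross-cohort replication
    tests on projected phenotypes, and window-based H3K27ac enhancer
    enrichment. A seeded synthetic-data module generates two-cohort
    landmark/genotype/coverage datasets with known planted effects so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    IRanges,
    GenomicRanges,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
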