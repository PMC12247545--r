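Package: SearchlightMVPA
Title: Cross-Participant Searchlight Decoding and Pattern-Dissimilarity
    Inference for Volumetric Brain Maps
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multivariate pattern analysis of per-subject, per-condition
    z-statistic brain volumes on a shared voxel grid. Implements a
    statistic-agnostic spherical searchlight engine; cross-participant
    three-way linear-SVM decoding scored by leave-one-subject-out
    cross-validation with resel-wise Bonferroni and exact binomial
    significance thresholds; a per-subject Euclidean pattern-dissimilarity
    searchlight on unit-normalised sphere patterns (values bounded by
    [0, 2]); and voxelwise brain-behaviour correlation of per-subject maps
    against trait covariates with threshold-free cluster enhancement (TFCE)
    and max-statistic permutation family-wise error control. A synthetic
    cohort generator produces spatially smooth multi-subject condition maps
    with seeded region patterns and optional trait coupling for validation
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    e1071,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
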