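Package: lordist
Title: Functional-Data-Analysis Distances for Longitudinal Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts sparse, irregularly sampled longitudinal microbial
    abundance tables into a subject-by-subject distance matrix by penalized
    basis-function smoothing of each subject-feature trajectory, per-feature
    functional principal component analysis (FPCA), eigenvalue-weighted
    score distances, and Euclidean aggregation across features. Includes
    total-sum-scaling normalization and prevalence/abundance filters for
    OTU tables, principal coordinates analysis and the PERMANOVA permutation
    test for downstream evaluation, a synthetic longitudinal-data generator
    with case/control taxon dynamics and sparsity injection for power
    studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    splines,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
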