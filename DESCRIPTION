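Package: EcoStates
Title: Cellular State and Ecotype Discovery from Cell-Type-Specific
    Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers transcriptionally defined cellular states per cell
    type by consensus non-negative matrix factorization with
    cophenetic-coefficient rank selection, groups co-occurring states into
    multicellular communities (ecotypes) via Jaccard/hypergeometric
    co-occurrence analysis and hierarchical clustering, assigns samples to
    ecotypes, recovers states and ecotypes in single-cell and spatial
    transcriptomics data with permutation z-scores, and provides the
    accompanying survival, ligand-receptor and gene-set enrichment
    statistics. Includes a seeded synthetic-cohort generator that plants
    known states, ecotypes and survival structure so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    survival,
    cluster,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, SingleCell, Spatial,
    Clustering, Survival
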