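Package: epiburden
Title: Regional Mutation Burden Modelling from Cancer Epigenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models megabase-scale somatic mutation burden in cancer genomes
    from chromatin-accessibility (ATAC-seq) and replication-timing (RepliSeq)
    profiles with random-forest regression. Provides a matched-split
    Monte-Carlo cross-validation test comparing cancer versus normal-tissue
    epigenomes as predictors, a permutation-refit null for forest feature
    importance with bootstrap confidence intervals, exact tree-path-dependent
    SHAP attributions, probabilistic per-window mutational-signature burden,
    residual-based prioritisation of hypermutated windows with gene
    annotation and enrichment tests, and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    ranger,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    emmeans,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
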