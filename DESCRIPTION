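Package: dexatlas
Title: Build and Query a Compendium of Differential Expression Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an atlas of consistently computed pairwise differential
    gene expression comparisons from count matrices and mixed sample
    metadata, and queries user gene lists against it. Covariates for each
    comparison are selected by correspondence analysis of doubled
    (Escoffier) and disjunctively coded metadata; differential expression
    uses a negative-binomial likelihood-ratio test with median-of-ratios
    normalization. Queries are scored at the gene, pathway, and
    transcription-factor-target level with ranked hypergeometric
    enrichment, empirical Brown p-value fusion, and fold-change
    correlation. Compendium-level analytics include comparison clustering,
    a differential-expression prior, and elastic-net feature extraction
    over fold-change matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
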