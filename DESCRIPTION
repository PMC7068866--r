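Package: phenoSamplers
Title: Sampling the Uncertainty Space of Gene Signatures in Binary
    Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring the uncertainty space of binary phenotype
    prediction from gene-expression data. Many distinct small gene
    signatures ("genetic networks") can classify a two-class phenotype with
    near-equal accuracy; this package samples that space with three
    complementary algorithms - a Fisher's-ratio sampler that draws genes
    with prior probability proportional to their Fisher's ratio, a holdout
    sampler that re-estimates a minimum-scale signature on many random
    75/25 train/validation bags, and a random sampler with a uniform prior
    over the differentially expressed genes. Signatures are scored by
    leave-one-out cross-validated k-nearest-neighbour accuracy, retained
    above an accuracy threshold, and summarised by a posterior
    gene-frequency analysis that yields ranked discriminatory gene lists
    and cross-sampler concordance. A synthetic-data generator with planted
    differentially expressed genes makes every step testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Classification, GeneExpression, FeatureExtraction, Microarray
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
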