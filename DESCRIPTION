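Package: dantx
Title: Multi-Stage Transcriptomic Inference for iPSC-Derived Dopaminergic
    Neuron Models of Parkinson's Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end reimplementation of a bulk RNA-seq inference workflow
    for induced pluripotent stem cell derived dopaminergic neurons carrying
    LRRK2 or Parkin mutations: median-of-ratios normalization, variance
    partitioning by PERMANOVA, negative-binomial Wald differential
    expression, differentiation-signature derivation from a reference time
    course, non-overlapping condition-signature intersection algebra,
    pre-ranked gene set enrichment analysis with permutation nulls,
    hypergeometric over-representation analysis, Markov clustering of
    protein-protein interaction networks, signed-hybrid co-expression
    networks with module eigengenes, and pathway-activity scoring with
    linear-model association. Ships a synthetic-data generator with planted
    ground truth emulating the study cohort so every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    limma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    fgsea,
    optparse,
    DESeq2,
    mclust,
    MASS
Config/testthat/edition: 3
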