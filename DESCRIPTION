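Package: jointGRN
Title: Joint Inference of Phenotype-Specific Gene Regulatory Networks from
    Single-Cell Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers one weighted transcription-factor-to-target gene
    regulatory network per ordered cell phenotype from imputed single-cell
    RNA-seq expression, by solving a joint LASSO problem in which an L1
    penalty enforces sparsity within each network and a fused quadratic
    penalty enforces similarity between the networks of consecutive
    phenotypes. Downstream utilities compute per-cell weighted regulon
    activity scores, minmax total-variation regulatory dissimilarity across
    phenotypes, Kleinberg authority and hub centralities of the inferred
    bipartite networks, and a synthetic benchmark (ternary network chains
    with negative-binomial transcription-factor expression) with micro-F1,
    Cohen's kappa and adjusted Rand index evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    mclust,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneRegulation, NetworkInference, SingleCell, Transcriptomics,
    GraphAndNetwork
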