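Package: regmetflux
Title: Integrated Transcriptional-Regulatory and Metabolic Modeling for
    Tumor Cohort Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Probabilistic integration of transcription-factor regulatory
    networks with genome-scale constraint-based metabolic models, in the
    PROM (probabilistic regulation of metabolism) tradition. Provides flux
    balance and flux variability analysis on top of a simplex linear
    programming backend, gene-protein-reaction rule parsing and evaluation,
    single-gene-deletion essentiality screens, transcription-factor knockout
    simulation via conditional-probability flux constraints, non-negative
    matrix factorization consensus clustering with cophenetic/silhouette
    rank selection, Kaplan-Meier estimation and k-sample log-rank testing,
    empirical-Bayes moderated-t differential expression, hypergeometric
    gene-set over-representation, cohort-level gene-essentiality consensus,
    and a four-type flux-reprogramming classifier. A synthetic-data module
    generates a fully self-contained toy cohort (metabolic model, regulons,
    expression, survival) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    cluster,
    limma,
    mclust,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
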