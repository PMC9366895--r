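Package: phenosim
Title: Cross-Species Phenotype Similarity and Disease-Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how model-organism phenotypes contribute to
    computational human disease-gene identification. Provides an integrated
    cross-species phenotype ontology model (OBO-subset parsing, equivalence
    bridging, subsumption closure), annotation corpora with true-path
    propagation and orthology transfer, information-content based Resnik
    similarity with best-match-average set comparison, random-walk and
    axiom-sentence ontology embeddings trained by skip-gram with negative
    sampling, supervised and naive gene-disease classifiers, a rank-based
    macro-averaged ROC evaluation protocol, annotation-bias diagnostics, and
    a synthetic benchmark generator with controllable study bias so that the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
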