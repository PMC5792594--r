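Package: ccminer
Title: Clade-Specific Gene Subfamily Mining and Candidate Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for discovering candidate biosynthetic genes by comparative
    mining of a protein superfamily across species: profile-based domain
    search with empirically calibrated E-values, pairwise-identity and
    neighbor-joining subfamily classification, calling of clade-specific
    subfamilies against a declared outgroup, expression-based candidate
    ranking, and Michaelis-Menten kinetics and fermentation yield
    accounting. A synthetic-data module generates multi-species proteomes,
    expression tables, and kinetic datasets with planted ground truth so the
    whole analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    phangorn,
    minpack.lm,
    jsonlite,
    yaml,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
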