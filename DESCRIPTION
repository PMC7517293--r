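Package: ptenet
Title: Direct Causality Networks from Multivariate Time Series by Partial
    Transfer Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directed interaction networks from multivariate time
    series with three conditional (direct) information-theoretic causality
    measures: partial transfer entropy on uniform delay embeddings (PTE),
    partial transfer entropy on non-uniform (mixed) embeddings selected by a
    greedy conditional mutual information criterion (PTENUE), and a variant
    whose term selection uses a low-dimensional approximation of conditional
    mutual information (LATE).  Mutual information and conditional mutual
    information are estimated with k-nearest-neighbor estimators under the
    maximum norm; significance is assessed with time-shifted surrogates.
    Includes generators for three benchmark systems with known ground-truth
    networks (a linear VAR, a nonlinear VAR, and coupled Henon maps), a
    sensitivity/specificity/F1 evaluation harness, and a benchmark runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
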