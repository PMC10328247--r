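Package: fuzzygrn
Title: Gene Regulatory Network Inference by Lagged MIC Screening and
    Fuzzy Activator-Repressor Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers signed, directed gene regulatory networks from
    time-series expression data in two stages. A pre-processing stage
    screens candidate regulators for every target gene with the lagged
    maximal information coefficient (MIC), computed by the ApproxMaxMI
    grid search. A Mamdani-style fuzzy model then scores every ordered
    activator-repressor pair from the screened candidates by how well
    the pair's combined regulatory effect (MIC-weighted expression)
    reproduces the target trajectory, ranking pairs by a residual score
    (mean squared error times rule-firing variance) and emitting signed
    edges. Includes DREAM-challenge format readers and writers, a
    planted-network simulator for end-to-end validation, and standard
    network-topology evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
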