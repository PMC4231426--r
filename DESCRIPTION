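Package: pgtr
Title: Regulatory Network Inference from Single-Gene Knockouts via
    Perturbation Graphs and Transitive Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs signed, directed gene regulatory networks from
    systematic single-gene-knockout expression compendia. Candidate edges are
    collected in a weighted signed perturbation graph built from z-scores of
    knockout-induced deviations and conditional correlations; indirect effects
    are then pruned by transitive reduction for weighted signed digraphs
    (TRANSWESD), by local transitive reduction restricted to feed-forward
    loops (LTR), or by reduction across strongly connected components
    (DR-FFL). The surviving edges are ranked into a confidence-sorted list of
    all ordered gene pairs and can be scored against a gold standard with
    precision-recall and ROC measures. A steady-state knockout simulator with
    separate biological and measurement noise provides self-contained
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
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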