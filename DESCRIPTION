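Package: rubiscokin
Title: High-Throughput Rubisco Carboxylation Kinetics from Plate-Reader
    Titration Assays
Version: 0.1.0
Authors@R:
    person("Rubisco", "Kinetics Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Infers per-active-site carboxylation rates (kcat,C) of form I
    rubiscos from NADH-coupled spectrophotometric plate-reader traces via
    CABP active-site titration, with quality control against an internal
    reference standard. Includes a synthetic-data generator for titration
    traces, variant panels and protein sequence families with known ground
    truth; greedy identity clustering for representative variant selection;
    nonparametric group comparisons (Mann-Whitney, Kruskal-Wallis, Dunn)
    with Q10 temperature correction; and exact Shapley feature attribution
    on depth-limited regression trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
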