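Package: aggrank
Title: Dominance Rank Inference and Strategic-Aggression Statistics for
    Directed Aggression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing timestamped dyadic aggression logs from
    animal social groups. Infers dominance rank from the directed
    aggression network via eigenvector-centrality power scores (with
    Weighted Simple Consensus and David's Score alternatives), builds a
    hierarchy-constrained null model that preserves each individual's
    power score on average and its total outgoing aggression exactly, and
    computes the rank-, magnitude- and motif-based statistics -- average
    rank aggression R(Delta), weighted rank difference W(n) and
    fractional transitivity T(n) over aggression chains -- that detect
    the emergence of strategic, rank-structured aggression. Includes a
    synthetic event-stream generator with configurable rank-dependent
    attack kernels, bootstrap uncertainty for event data, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
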