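Package: netmotif
Title: Network Motif Detection by Exhaustive Subgraph Census
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects k-node network motifs (3 <= k <= 6) in directed networks
    by exhaustive induced-subgraph census against degree-preserving random
    ensembles. Subgraphs are classified without an external isomorphism
    package: canonical labels for all loop-free digraphs on up to five nodes
    are precomputed in a pretreatment phase, and six-node subgraphs are
    classified through the deck of their vertex-deleted five-node cards with
    an explicit isomorphism fallback. Provides four degree-preserving
    switching null models differing in their treatment of bidirectional
    edges, a uniform configuration-model sampler, frequency, concentration,
    Z-score and empirical p-value statistics, and a command-line interface
    that reads plain-text edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
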