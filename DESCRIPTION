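Package: phagenet
Title: Gene Co-Occurrence Networks for Bacteriophage Host-Range Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genome- and gene-level co-occurrence networks from
    bacteriophage proteomes via a binary genome-by-gene-cluster membership
    matrix, partitions them with a from-scratch Markov Cluster (MCL)
    implementation selected by the intracluster clustering coefficient,
    relates network topology to host phylogeny (abundance-weighted mean
    pairwise phylogenetic distance, shortest paths, neighborhood
    similarity), maximizes the mutual information between graph clusters
    and host genera with the constrained greedy 'mimax' search, and
    predicts phage hosts by a leave-one-out majority-host criterion.
    Includes a synthetic-data generator emulating phylogenetically
    structured gene sharing for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Biostrings,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    picante,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
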