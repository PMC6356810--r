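Package: ncmnet
Title: Characteristic-Gene Identification in Interaction Networks with
    the Normalized Centrality Measure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens differentially expressed genes from two-group
    log2 expression matrices (per-gene t-tests with Benjamini-Hochberg
    adjustment and fold-change thresholds), integrates DEG calls across
    datasets, builds weighted undirected gene interaction networks from
    STRING-style edge lists, computes five classical node centralities
    (degree, betweenness, closeness-as-farness, clustering coefficient,
    eccentricity) together with the composite Normalized Centrality
    Measure (NCM), mines high-density subgraphs by seeding on maximal
    clique centrality (MCC) hubs and expanding under a cliqueness
    threshold, and performs offline hypergeometric gene-set enrichment
    against GMT collections. Seeded synthetic generators for expression
    matrices with planted fold changes and random graphs with planted
    dense modules make the whole pipeline testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
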