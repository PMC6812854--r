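Package: metanet
Title: Evolutionary Analysis of Bipartite Metabolic Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study the evolutionary growth of metabolic networks from
    integrated tables of enzymes, KEGG pathway hierarchy, SCOP fold-family
    domains and phylogenomic domain ages. Builds age-sliced bipartite networks
    linking enzymes to pathway subnetworks or mesonetworks, derives their
    weighted one-mode projections, and applies a statistical battery to every
    slice: discrete power-law fits with Kolmogorov-Smirnov model selection,
    the Bartels rank von Neumann randomness test, small-world coefficients
    against Erdos-Renyi ensembles, fast-greedy modularity, hierarchical
    C(k) ~ k^-1 scaling, and node centralities. Includes enzyme recruitment
    analyses (sharing matrices, Ward clustering, modularity heatmaps) and
    taxonomic, functional and catalytic-site distributions, plus a seeded
    synthetic-data generator emulating the statistical structure of the real
    enzyme-pathway data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ape,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
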