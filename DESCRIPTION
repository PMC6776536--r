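Package: gincompare
Title: Comparative Analysis of Genetic Interaction Networks Across Genetic
    Backgrounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing chemical-genetic and genetic interaction
    networks (GINs) measured in multiple genetic backgrounds of a model
    organism. Converts arrayed colony-size screens into growth-ratio
    Z-score interaction profiles with linkage-group exclusion, assembles
    augmented networks by bounded-hop expansion of screen hits into a
    weighted global interaction network, partitions them into communities
    by Louvain modularity maximisation, ranks genes by betweenness,
    closeness and eigenvector centrality to identify network bottlenecks,
    and summarises communities and centrality clusters by Gene Ontology
    term coverage, hypergeometric enrichment with two-stage
    Benjamini-Krieger-Yekutieli FDR control, Lin semantic similarity and
    REVIGO-style uniqueness, and SAFE-style spatial enrichment. Includes
    a synthetic-data generator (plates, planted hypersensitive genes,
    planted-partition global networks, toy GO DAGs) so the full study
    design can be exercised end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    cluster,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
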