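Package: conceptmapr
Title: Group Concept Mapping: Card-Sort Similarity, Nonmetric Scaling,
    Cluster Maps and Rating Pattern Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for group concept mapping studies. Aggregates
    participant card-sort partitions into statement-by-statement co-occurrence
    similarity matrices, embeds them in two dimensions by nonmetric
    multidimensional scaling with Kruskal stress-1 (monotone regression via
    pool-adjacent-violators), clusters the resulting point map with Ward
    hierarchical agglomeration, suggests cluster labels from participant pile
    titles, aggregates Likert importance ratings per statement and cluster,
    and compares stakeholder groups with pattern matches. Includes a
    synthetic sort-and-rate generator with planted cluster structure for
    validation, and a packaged example of a 70-statement study of barriers to
    medication for opioid use disorder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
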