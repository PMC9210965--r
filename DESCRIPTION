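Package: domtax
Title: Protein Domain Based Species Classification with Minimum Spanning Trees
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A standardized three-step framework for classifying species by
    protein-domain evidence. Per-species domainome profiles are built from
    pfam_scan-style domain-hit tables under four statistical models (domain
    content, domain organization, and their frequency-weighted variants),
    pairwise species distances are computed under Jaccard, Poisson, and
    loss-corrected models, and species are arranged on a minimum-cost
    spanning tree built with Prim's algorithm. The tree is clustered against
    a reference taxonomy at a chosen rank and agreement is scored with three
    standards: the arithmetic percentage of isolated species, the weighted
    percentage, and the number of split taxa. Includes a CheckM-style
    assembly quality filter, readers and writers for domain-hit tables,
    taxonomy tables, distance matrices (TSV and square PHYLIP) and
    Cytoscape-importable JSON edge lists, and a seeded domainome simulator
    with known clade structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
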