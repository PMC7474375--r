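Package: netpharm
Title: Network Pharmacology of Syndrome-Related Biomolecular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network-pharmacology analysis of traditional-medicine
    syndromes and herbal formulae: phenotype-driven gene prioritization by
    concordance between phenotype-similarity profiles and network-closeness
    profiles, with degree-preserving permutation validation; druglikeness
    filtering by weighted quantitative estimate of druglikeness (wQED) and
    compound-target prediction by concordance with drug-relevance profiles;
    exact Poisson-binomial significance of herb-level target occurrence;
    gene-set enrichment, differential-expression overlay onto network
    modules, and degree-matched topological proximity of target sets.
    Includes seeded synthetic-data generators with planted ground truth for
    end-to-end benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
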