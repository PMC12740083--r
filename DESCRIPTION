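Package: phylodeg
Title: Phylostratigraphic Enrichment Analysis of Differentially Expressed Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps gene sets onto a 19-level ordinal scale of evolutionary age
    (phylostrata) and tests each stratum for over- or under-representation of
    differentially expressed genes against a genome-wide gene universe using
    one-tailed hypergeometric probabilities with Benjamini-Hochberg false
    discovery rate correction. Quantifies the mean evolutionary age shift of a
    gene set with a tie-aware Mann-Whitney rank test, summarises up/down
    direction heterogeneity across datasets, and ships a seeded synthetic-data
    generator (biased weighted sampling of gene sets from a configurable
    universe) so the whole pipeline, including type-I calibration and
    parameter recovery, can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
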