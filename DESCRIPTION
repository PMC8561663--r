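Package: nemacomm
Title: Neutral-Model Analysis of Per-Host Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-ecology analysis of per-host bacterial count tables
    (CFU per individual host, as in Caenorhabditis elegans gut microbiome
    experiments). Fits the Dirichlet-multinomial neutral sampling model by
    maximum likelihood, simulates structure-matched null data sets (same
    hosts, same per-host totals), and tests empirical interspecies Spearman
    correlation quantiles against the neutral null. Also provides Shannon
    diversity versus population-size regression with likelihood-ratio
    comparison across host lineages, log-transform/standardization, PCA,
    Bray-Curtis distances, ANOSIM and PERMANOVA, and a synthetic-data
    generator for neutral and interacting communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    MASS
Suggests:
    readxl,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
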