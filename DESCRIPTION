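Package: chromhub
Title: Integrative 3D-Genome Topology of Regulatory Elements and Disease Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating chromatin topology (contact matrices,
    TADs, A/B compartments, diamond insulation scores, chromatin loops)
    with regulatory annotation (chromatin-state derived cis-regulatory
    elements, ROSE-style super-enhancer calling from H3K27Ac coverage),
    resampling-based enrichment tests against random region and random
    TAD nulls, topological classification of eQTL variant-eGene pairs
    (promoter/distal, compartment, same-TAD, promoter-interacting eQTL
    taxonomy), and GWAS variant-to-target-gene linking via loops and
    shared regulatory elements. Ships a fully seeded synthetic-genome
    generator with planted truth labels so every pipeline stage is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    IRanges,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
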