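Package: panchrom3d
Title: Pan-Genome Chromatin Architecture and Structural Variant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for pan-3D genome analysis across many
    genome assemblies of one species. Classifies genomic and chromatin features
    (gene families, structural variants, TAD boundaries, chromatin loops,
    long-range cis-regulatory elements) into core, softcore, dispensable and
    private conservation categories on a shared backbone coordinate system;
    calls insulation-score TAD boundaries, A/B compartments and map resolution
    from binned Hi-C contact matrices; merges, mechanism-types and
    hotspot-screens structural variants; runs bootstrap coverage
    enrichment/depletion tests, Weir-Cockerham Fst and nucleotide-diversity
    selection screens; and calls differential Capture Hi-C interactions.
    Includes a synthetic multi-genome data generator with planted ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
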