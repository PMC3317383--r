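Package: ptmtalk
Title: Posttranslational-Modification Crosstalk Site Calling on Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate sites of crosstalk between protein
    posttranslational modifications from per-residue predictor scores and
    ortholog alignments. Classifies Ser/Thr/Tyr residues by their
    phosphorylation and O-beta-GlcNAc status into Yin Yang (both channels
    above threshold) and false-negative Yin Yang (one channel above, the
    other near threshold, at conserved positions) sites, applies selection
    filters based on experimental support, evolutionary conservation and
    surface accessibility, scans kinase recognition motifs with
    percentile-ranked position weight matrices, calls consensus methylation
    sites across multiple predictors, transfers known sites between
    homologs through global alignment, and annotates neighbor crosstalk
    between methylation and phosphorylation sites. Ships a curated human
    FoxO3 regression fixture and seeded synthetic-data generators for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
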