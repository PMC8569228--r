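Package: evasinclass
Title: Identification and Classification of Tick Evasin-Like Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying and classifying tick salivary
    chemokine-binding proteins (evasins) and their transcriptome-derived
    homologs. Derives mature proteins from precursor sequences via a
    first-methionine rule and a pluggable signal-peptide cleavage provider,
    screens candidates against characterized evasins with Smith-Waterman
    local alignment and Karlin-Altschul E-values, profiles cysteine counts
    and PROSITE-style cysteine-spacing motifs (Cys6 and Cys8 frameworks),
    builds neighbour-joining trees from square-root identity distances with
    column-resampling bootstrap support and midpoint rooting, and assigns
    class labels (A1/A2, B1/B2, B1.1/B1.2) from the clades descending from
    the root. Includes a synthetic-data generator that emulates signal
    peptides, planted cysteine frameworks, two-lineage divergence and decoy
    records so every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
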