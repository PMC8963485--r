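Package: hybridtrace
Title: Hybrid Detection and Introgression Analysis for Sympatric Wild Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects natural hybrids between two sympatric AA-genome wild
    rice taxa and characterises their origin from whole-genome variant
    data. Implements per-sample variant classification and heterozygosity
    statistics, chloroplast typing against two reference plastomes with
    cytonuclear-concordance (chloroplast capture) classification,
    diagnostic-locus allele-additivity calls, hybrid-generation inference
    from genome-wide heterozygosity, the four-taxon ABBA-BABA test with
    Patterson's D and a block-jackknife Z test, and population-structure
    analyses (LD pruning, PCA, Nei genetic distance, Mantel
    isolation-by-distance). A synthetic-data module simulates parental
    populations, F1/backcross hybrids with either chloroplast donor, and
    four-taxon alignments with tunable introgression, so the whole
    pipeline is testable without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    Biostrings,
    vegan,
    geosphere,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
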