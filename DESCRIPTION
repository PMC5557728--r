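Package: satlib
Title: Satellite DNA Library Analysis from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines full-length satellite DNA monomers directly from
    whole-genome paired-end short reads against a family consensus, and
    quantifies the satellite "library" shared between related species:
    haplotype tallies with singleton filtering, haplotype and nucleotide
    diversity (DnaSP-style, indel-aware), per-column sequence-logo
    information content, CD-HIT-style greedy clustering at a sequence
    identity threshold, and abundance-weighted minimum spanning trees of
    haplotypes with explicit mutational-step nodes. Includes a simulator of
    satellite library evolution (shared ancestral variants, per-species
    differential amplification, tandem arrays, paired-end reads) so every
    stage can be validated against known ground truth, plus in-silico PCR
    with degenerate IUPAC primers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
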