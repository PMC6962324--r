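Package: phagestrain
Title: Strain-Level Diversity and Transmission of Gut Phages from Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for strain-level analysis of crAss-like bacteriophage
    populations in shotgun metagenomes: presence calling from classified
    read counts, pileup-based fixed-SNP and multiallelic site calling, the
    coverage-normalised F_multi diversity statistic, codon-level variant
    effect prediction with an equal-probability mutation null model and
    likelihood-ratio enrichment tests, sliding-window genome profiles,
    pairwise genome comparison by anchor chaining, vertical-transmission
    classification, and a synthetic cohort simulator with known ground
    truth for mother-infant and FMT study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
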