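Package: dctpaint
Title: Chromosome Painting of Mosaic Genomes Produced by Distributive
    Conjugal Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the mosaic genomes that mycobacterial
    distributive conjugal transfer (DCT) produces. Simulates divergent,
    collinear parental genome pairs and ground-truth transconjugants,
    assigns parental origin to nonoverlapping 500-bp windows of a
    transconjugant genome by identity scoring against both parents,
    concatenates same-origin windows into transferred segments, and
    summarises per-transconjugant and cohort statistics (percent parental
    DNA, number and size of transferred regions). Also provides pairwise
    SNV distance matrices, windowed SNV-density tracks, and locus-level
    comparisons (global protein percent identity, locus SNV catalogues
    with coding effects).
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
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
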