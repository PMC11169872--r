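Package: cream
Title: Comparative Restriction Enzyme Analysis of Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of Comparative Restriction Enzyme
    Analysis of Methylation (CREAM) experiments. CREAM profiles CpG
    methylation by sequencing two reduced-representation libraries per
    sample, digested in parallel with the isoschizomers MspI
    (methylation-insensitive) and HpaII (blocked by CpG methylation at
    CCGG), each anchored by the rare cutters NsiI and PstI. The package
    provides deterministic in-silico digestion with closed-form cut-spacing
    theory, a seeded generator of synthetic clonal-population experiments
    with ground-truth methylation status, the methylotyping pipeline that
    reconstructs sequenced inserts from paired-end alignments, calls
    population loci and classifies each locus per sample as unmethylated,
    MspI-only, length-shifted or HpaII-only, and population-level summaries:
    methylation frequency spectrum, principal component analysis, rank tests
    against subculture number, genomic density correlation and gene-set
    enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
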