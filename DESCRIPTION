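Package: poolinv
Title: Chromosomal Inversion Frequencies and Dynamics from Pool-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers chromosomal inversion frequencies from pooled sequencing
    (Pool-Seq) data using inversion-diagnostic marker SNPs. Provides paternal
    haplotype reconstruction from F1 hybrids sequenced against a homozygous
    reference strain, discovery of fixed differences between inverted and
    non-inverted chromosome arrangements, marker-averaged inversion frequency
    estimation from PoPoolation-style sync files with coverage filtering,
    replicate-aware Cochran-Mantel-Haenszel and Fisher exact testing of
    frequency change, arrangement-stratified nucleotide diversity, F_ST and
    linkage disequilibrium statistics, a Wright-Fisher neutral null with
    empirical p-values for observed frequency changes, and seeded synthetic
    data generators with known truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
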