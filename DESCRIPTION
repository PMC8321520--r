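Package: popgenpipe
Title: Population-Genomic Pipelines from VCF to Demographic-Inference Inputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidyverse-native toolkit for population-genomic workflows that
    start from a phased VCF and end at the input files of demographic-inference
    software. Provides a JSON population-model file format, site- and
    locus-level VCF filtering, windowed Tajima's D and Weir-Cockerham FST,
    statistic-binned locus subsampling, four-gamete-test extraction of
    recombination-free haplotype blocks, BED interval algebra, per-haplotype
    sequence reconstruction from a reference FASTA, multi-dimensional site
    frequency spectra, and writers for the IMa3, G-PhoCS, dadi, treemix,
    fastsimcoal2, EIGENSTRAT and PED/MAP formats. A seeded synthetic-data
    module generates reference + VCF + BED + model fixtures with known truth
    for testing whole pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
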