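Package: hapdeficit
Title: Recessive Lethal Haplotype Discovery from Deficit of Homozygosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping recessive lethal haplotypes in livestock
    populations from phased SNP genotypes. Implements marker quality control
    (call rate, minor allele frequency, exact Hardy-Weinberg test), a
    sliding-window deficit-of-homozygosity scan with an exact binomial test,
    litter-based validation of candidate haplotypes (farrowing and pre-weaning
    survival by mating class), linkage-disequilibrium prioritisation of
    sequence variants against the haplotype, and a minimal coding-consequence
    annotator for stop-gained candidates. Includes a gene-drop simulator of a
    closed breeding population with an implanted recessive lethal haplotype
    for end-to-end testing without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
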