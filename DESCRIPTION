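Package: sexscan
Title: Sex-Determining Locus Discovery from Family and Pooled Sequencing Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome scans for sex-linked variation in fish with homomorphic
    sex chromosomes, built around the wild Nile tilapia LG23 XY system.
    Provides family-based association scans (per-site Weir-Cockerham FST and
    two-sided Fisher's exact tests on sexed offspring), XY/ZW inheritance
    classification with recombination-breakpoint reporting, pooled
    whole-genome-sequencing scans with Sex-SNP-Finder-style XY/ZW allele
    frequency criteria, detection and masking of high-coverage B-chromosome
    blocks, read-depth change-point estimation of structural-variant
    breakpoints, reconstruction of the Y-specific amh tandem-duplication
    haplotype, and variant effect annotation against gene models. A seeded
    synthetic-data module simulates families, sex pools and depth profiles
    with the statistical structure the analyses assume, so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
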