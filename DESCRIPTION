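Package: greyCNV
Title: Genotyping and Population Analysis of a Tandem Intronic Copy Number
    Variant at the Horse Grey Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving a tandem intronic copy number variant (CNV)
    into an allelic series and analysing it end to end: read-depth and
    droplet digital PCR (ddPCR) copy-number estimation, pedigree-constrained
    deduction of per-chromosome allele copy numbers with detection of
    de novo copy-number mutation events, exact small-sample association
    statistics (Fisher, chi-squared goodness of fit, a dominance-model
    genome scan), an opposite-homozygote sliding-window identity-by-descent
    scan with run-of-homozygosity calling from pileup diversity, typing of
    CNV alleles from long spanning reads (length classification, binning and
    consensus, tandem structure detection, junction microhomology), CpG
    methylation profile construction and smoothing, and allele-frequency
    deduction from breed-level copy-number histograms. A full synthetic-data
    generator produces every input the pipeline consumes, so all stages are
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
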