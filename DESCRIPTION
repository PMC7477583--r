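Package: teapop
Title: Variant Filtering, Diversity Statistics and Selective Sweep
    Scanning for Plant Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genomic analysis of diploid resequencing data
    built around a strict SNP filter cascade (GATK-style hard filter plus
    indel-proximity, consensus-quality, biallelic, depth-percentile and
    minor-allele-frequency criteria), sliding-window heterozygosity and
    nucleotide diversity with a subsampling protocol, Tajima's D,
    Weir-Cockerham Fst, linkage-disequilibrium decay with a half-decay
    statistic, a composite-likelihood-ratio selective sweep scan with
    frequency-spectrum backgrounds and region merging/scoring, and
    Kimura two-parameter / Ks molecular dating. Includes a seeded
    synthetic-data generator (neutral frequency spectra, implanted hard
    sweeps, VCF artifacts, K2P-evolved sequence pairs) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
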