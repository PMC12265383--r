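Package: coldscan
Title: Two-Population Selective Sweep Scans with Synthetic Haplotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate genes under recent positive selection by
    contrasting a focal population against a reference population with an
    outgroup panel for allele polarization. Implements four complementary
    window/gene-level statistics (Hudson Fst with the log2 nucleotide
    diversity ratio, a cross-population composite likelihood ratio scan,
    the iHH12 extended haplotype homozygosity integral, and an HKA-like
    polymorphism-versus-divergence test), empirical-percentile outlier
    calling with a three-of-four intersection rule, derived allele
    frequency difference ranking of top variants per effect class, and
    identity-by-state distances with neighbor-joining trees. Ships a
    deterministic haplotype simulator (Balding-Nichols background plus an
    injectable hard sweep) emitting VCF, population map, and gene
    intervals so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    IRanges,
    S4Vectors,
    jsonlite,
    pracma,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
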