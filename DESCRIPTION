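Package: mitofounder
Title: Founder Analysis and Rho-Statistic Dating of Mitochondrial DNA Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mitochondrial DNA phylogeography. Scores variants
    against a mitogenome reference in rCRS coordinates with the community
    exclusion filters, builds reduced-median haplotype networks and resolves
    them into rate-weighted most-parsimonious mutation trees, dates clades
    with the rho statistic and Saillard standard errors under calibrated
    molecular clocks, identifies founder lineages between a source and a
    sink population under f0/f1/f2 criteria, scans migration times on a
    200-year grid, allocates founder clades probabilistically to stipulated
    migration events, computes skyline increment ratios, and simulates
    coalescent founder-pulse scenarios with known demographic truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
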