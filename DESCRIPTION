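Package: sweepaxes
Title: Selection-Signature Scans on Phased Haplotypes and Their Summary
    into Canonical Axes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes nine per-SNP selection-signature statistics on phased
    multi-population haplotype data (Tajima's D, Fay and Wu's H, Fu and Li's
    D*, iHS, nSL, H12, windowed pairwise FST, XP-EHH and VarLD), summarizes
    the resulting score tracks into three varimax-rotated canonical axes by
    principal-axis factor analysis, and calls candidate selection regions
    and genes from empirical-outlier thresholds. Includes a forward
    Wright-Fisher simulator of multi-population phased haplotypes with
    known ancestral alleles and optional selective sweeps, used as the test
    substrate for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
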