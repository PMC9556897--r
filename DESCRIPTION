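Package: plastidscreen
Title: Comparative Plastome Structural Variation and Marker Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative analysis of chloroplast (plastome) genomes aimed at
    screening phylogenetic markers. Detects the quadripartite LSC/IRb/SSC/IRa
    structure and region junctions, scans simple sequence repeats and dispersed
    forward/palindromic repeats, tabulates SNPs and indel events from a whole
    genome alignment with per-region tallies and pairwise ALS/indel matrices,
    computes sliding-window nucleotide diversity (Pi) with Pi-threshold species
    grouping, vets candidate genes by codon-usage bias (RSCU, GC3s, ENC against
    the expected ENC-GC3 curve), applies length/SNP ideal-marker criteria to
    per-gene statistics, and diagnoses per-marker tree conflict with
    neighbor-joining trees and Robinson-Foulds distances. Includes a plastome
    evolution simulator (region-specific rates, indels, SSR loci, concerted
    inverted repeats, true alignment and event logs) so the whole pipeline is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
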