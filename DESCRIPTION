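Package: superbarcode
Title: Comparative Plastome Analysis and Whole-Genome Super-Barcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated chloroplast genomes
    aimed at species identification by "super-barcoding": parsing GenBank
    plastome records, detecting the quadripartite (LSC/IRa/SSC/IRb) structure,
    classifying multiple-alignment columns, computing pairwise base-difference
    matrices and per-region divergence statistics, excising barcode markers by
    in-silico PCR with IUPAC-degenerate primers, scoring per-marker species
    discriminability from diagnostic SNPs, and building neighbor-joining trees
    with column-bootstrap support. Includes a sequence-evolution simulator
    that generates annotated plastome sets with known substitution and indel
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
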