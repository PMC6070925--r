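Package: malminer
Title: Mining and Classification of MAL Gene Clusters in Yeast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects MAL gene clusters (alpha-glucosidase, alpha-glucoside
    transporter and MAL-activator genes) in annotated yeast genomes, extracts
    the nine-residue GH13 alpha-glucosidase signature anchored to S. cerevisiae
    IMA1 numbering through pairwise global alignment, predicts substrate
    specificity (maltase, isomaltase or promiscuous maltase-isomaltase) by
    motif and nearest-reference rules, and builds neighbor-joining phylograms
    of the encoded proteins with Dayhoff-model distances and bootstrap
    support. Ships a seeded synthetic-genome generator so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
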