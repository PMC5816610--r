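Package: cassettecompare
Title: Comparative Genomics of Gene Cassettes, Regulatory Footprinting and
    Relative Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting gene function from chromosomal context in
    bacteria. Assembles gene cassettes from annotated replicons by an
    intergenic-distance rule, fingerprints cassettes with truncated Enzyme
    Commission numbers and functional roles, quantifies functional-content
    matches between cassettes by maximum bipartite matching, and searches a
    cassette database for function combinations conserved across taxonomic
    groups. Includes a phylogenetic-footprinting toolkit (intergenic-region
    extraction, center-star multiple alignment, per-column conservation,
    position-weight-matrix scanning in transcription-start-relative
    coordinates, and score/conservation ranking of candidate binding sites),
    delta-delta-Ct relative quantification of qPCR data, and seeded
    synthetic-data generators with recorded ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
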