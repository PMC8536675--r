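Package: crisprbarcode
Title: Design and Evaluate Species-Discriminating Cas12a Guides on DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing Cas12a crRNAs that discriminate plant species
    from a DNA-barcode locus (such as chloroplast trnL). Scans a target species
    for TTTV protospacer-adjacent motifs on both strands, projects each
    candidate spacer through a multiple alignment onto every other species,
    scores PAM conservation and seed/distal spacer mismatches, predicts the
    qualitative collateral-cleavage readout per species under configurable
    activity rules, and ranks candidates by discrimination power. Also locates
    RPA primers and predicted amplicons, builds T7 in-vitro-transcription
    constructs, evaluates blinded panels with confusion-matrix accuracy and
    precision, and generates fully synthetic barcode panels with planted
    ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
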