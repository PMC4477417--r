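Package: propalign
Title: Protein Sequence Alignment from Weighted Biochemical Property Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global pairwise alignment of protein sequences that minimizes a
    distance built from weighted, min-max normalized biochemical property
    profiles (hydrophobicity, size, coil propensity, thiol group by default)
    instead of a 20x20 substitution matrix. Includes a conventional
    maximal-similarity matrix-based global aligner as a baseline, reference
    alignment accuracy metrics (developer/modeler-style Q scores), a grid
    search optimizer for property weights and affine gap penalties, a
    synthetic benchmark generator producing homologous sequence pairs with
    known true alignments, and a command line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
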