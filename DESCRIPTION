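Package: pairdca
Title: Inter-Protein Coevolution Analysis by Mean-Field Direct Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds spacer-concatenated paired alignments of two interacting
    proteins, fits a mean-field inverse Potts (direct coupling analysis)
    model with sequence reweighting and pseudocounts, computes mutual
    information and direct information for all residue pairs, filters and
    ranks co-varying inter-protein pairs against anchor residues, and
    annotates ranked pairs with inter-residue distances measured on a
    docked complex structure. Includes a planted-coupling synthetic
    paired-alignment generator with closed-form oracles for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
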