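Package: nodulomics
Title: Mass Arithmetic, Feature Attribution and Community Recovery for a
    Root-Nodule Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for discovering nonribosomal peptides in a
    simplified legume root-nodule microbiome. Provides exact monoisotopic mass
    arithmetic for elemental formulas, peptides with nonstandard termini
    (N-formyl, C-terminal ethanolamide, cyclic backbones) and electrospray
    adducts; a/b/x/y fragment-ion prediction and ladder-walk de novo
    sequencing of linear nonribosomal peptides; grouping of MS1 ions into
    neutral-mass hypotheses across proton/sodium adducts; a nested subtractive
    Venn analysis attributing LC-MS features to individual community members;
    Stachelhaus-code comparison of NRPS adenylation domains; and recovery-rate,
    CFU and interaction analysis of nodule isolation tables. A seeded
    synthetic-data module generates feature tables, MS2 spectra and
    colonization tables so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
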