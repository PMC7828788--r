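Package: allerscreen
Title: In Silico Digestion and Allergenic Versus Tolerogenic Screening of
    Food-Protein Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based simulation of gastrointestinal proteolysis (pepsin,
    trypsin, chymotrypsin specificity tables in the P4-P4' positional
    nomenclature), mapping of surviving peptides onto curated IgE and T-cell
    epitope intervals, threshold classification of MHC class II binding
    affinities (pIC50 and IC50 scales), ingestion of cytokine-induction and
    bioactivity predictor summaries, and an integrated 16-factor radial-area
    score that contrasts allergenic against tolerogenic peptide potential.
    Ships curated cow's-milk allergen tables and a seeded synthetic-data
    generator with planted ground truth, plus replicate-homogeneity checks
    for mass-spectrometry identification summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
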