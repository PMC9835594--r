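Package: ubselex
Title: Occurrence of Unnatural-Base DNA Aptamer Candidates in SELEX Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combinatorial analysis of DNA aptamer selection (SELEX) libraries
    built on the expanded genetic alphabet with the hydrophobic unnatural base
    pair Ds-Px. Models the three library designs used for Ds-DNA aptamer
    generation (natural randomized, Ds-predetermined sublibrary sets, and
    Ds-doped five-letter randomized), computes the required sequence-space
    number for an aptamer candidate motif and its expected occurrence in an
    initial library of given complexity, validates the closed-form results
    against exhaustive enumeration and seeded Monte Carlo sampling, and
    implements the electrophoresis mobility shift assay (EMSA) quantification
    pipeline that calls important base positions from band densities, together
    with the mutational variant-set designers (transition mutations and
    single-position Ds substitutions) that feed it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
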