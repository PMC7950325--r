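Package: oxlink
Title: Mapping Oxidant-Induced Protein Modifications and Cross-Links from
    Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping oxidative post-translational modifications
    and covalent protein cross-links from bottom-up proteomics data.
    Implements in-silico tryptic digestion, peptide and cross-linked-pair
    mass arithmetic (di-tyrosine, di-tryptophan and tyrosine-tryptophan
    links with a -2 H mass delta), 16O/18O proteolytic-label doublet
    classification separating linear (+4 Da) from cross-linked (+8 Da)
    peptides, fragment-ion matching and target-decoy scoring of
    cross-linked candidates, per-residue relative site occupancy (RSO)
    quantification from MS1 areas, two-condition conformational footprint
    comparison, and mapping of sites and cross-links onto protein
    module/domain architecture. A seeded synthetic-data generator produces
    ground-truth-known feature tables and spectra so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
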