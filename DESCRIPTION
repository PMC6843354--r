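Package: xlhdx
Title: Integrative Cross-Linking Mass Spectrometry and Hydrogen-Deuterium
    Exchange Analysis of Protein-DNA Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing transcription-factor/DNA complexes by
    integrative mass spectrometry. Implements in-silico proteolytic and
    nucleolytic digestion, monoisotopic mass computation for peptides,
    oligonucleotides and cross-linked conjugates (NHS-ester linkers and
    platinum adducts), annotation of deconvoluted intact-mass spectra,
    theoretical cross-link library construction and ppm matching,
    isotope-doublet (d0/d4) quantification of free-versus-bound cross-link
    partitioning, hydrogen-deuterium exchange uptake analysis with
    residue-level consolidation and differential protection calling, and
    conversion of identifications into distance restraints that can be
    validated against 3D structures. A seeded synthetic-data generator
    produces ground-truth scenarios (folds, planted cross-links, noisy peak
    lists with decoys, exchange kinetics) for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
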