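Package: pairPSSM
Title: Pair Position-Specific Scoring Matrices for Inferring Homologous
    Protein-Protein Interactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds contact position-specific scoring matrices (pairPSSMs)
    from a three-dimensional dimer template and two paired evolutionary
    profiles, scores candidate protein pairs by normalized specific
    interfacial energy, and evaluates ranked interaction screens with
    average-precision, false-positive and balanced error-rate statistics.
    Includes interface contact extraction from PDB/mmCIF structures,
    template quality control, interacting-domain mapping, pair-coverage
    analysis of related dimers, and deterministic synthetic fixture
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
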