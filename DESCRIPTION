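Package: specswitch
Title: Structure-Based Design of Complex-Specificity Switch Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies residues of a shared protein subunit that bind one
    complex-specific partner but not another, and designs mutations intended
    to abolish one complex state while preserving the other. Provides
    template-based complex modelling by alignment-guided coordinate grafting,
    Kabsch superposition, clash-relieving rigid-body shifts, heavy-atom
    contact maps, differential interface identification, Shrake-Rupley
    solvent-accessible surface area, orthologue-gap (unique loop) detection
    from multiple sequence alignments, rule-based mutation proposal with a
    rotamer-based steric clash score, and enumeration of grouped mutant
    combinations. Includes a synthetic fixture generator that builds toy
    helical complexes with known ground-truth interfaces so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
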