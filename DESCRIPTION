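Package: pepconj
Title: Conformational Screening of Modular Self-Assembling Peptide-Drug
    Conjugates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the rational design of enzymatically activated
    self-assembling peptide-drug conjugates. Represents modular conjugates
    (targeting/tailoring, assembly, drug and extending modules around the
    amyloid-derived KLVFFAE motif), reads and writes multi-model PDB
    conformational ensembles, computes Shrake-Rupley solvent-accessible
    surface area with a deterministic spiral lattice, Kabsch superposition
    and RMSD series, radius of gyration and Ramachandran-rule secondary
    structure, detects hydrogen bonds, salt bridges and hydrophobic
    contacts and aggregates them into module-pair interaction landscapes,
    scores the solvent exposure of the assembly module (%SASA) with a
    dispersity threshold and the exposure change on caspase-3/7 (DEVD)
    cleavage, and estimates critical aggregation concentrations from
    Thioflavin T titrations by two-segment breakpoint regression. Includes
    generators for ideal-geometry synthetic conformations with planted
    contacts and for synthetic titration curves, and an end-to-end design
    screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
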