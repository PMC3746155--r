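Package: lipidprint
Title: Protein-Lipid Contact Fingerprints and Annular Lipid Analysis for
    Membrane Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Per-residue lipid contact fingerprinting for membrane proteins
    from coordinate trajectories and lipid-containing crystal structures.
    Computes head-group and acyl-tail contact frequency profiles at
    atomistic (4 Angstrom) or coarse-grained (6 Angstrom) cutoffs, Pearson
    correlations between contact profiles from different data sources,
    in-plane phosphate density and local bilayer thickness (P-P distance)
    maps with bulk and annular summaries, per-lipid fractional contact
    times and binding-event statistics, residue-type by lipid-segment
    interaction tables normalised by residue occurrence, and projection of
    contact conservation onto a family sequence alignment. Includes a
    seeded synthetic membrane-trajectory generator with closed-form ground
    truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    graphics,
    tools,
    stats,
    utils,
    bio3d,
    Biostrings
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Lipidomics, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'scheme.R'
    'neighbors.R'
    'contacts.R'
    'geometry.R'
    'io.R'
    'methods-accessors.R'
    'msa.R'
    'residence.R'
    'residue-stats.R'
    'synthetic.R'
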