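Package: CrystalContacts
Title: Structural Dissection of Protein-Protein Crystal Packing Contacts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing protein-protein crystal packing contacts in
    monomeric protein crystal structures. Enumerates packing contacts by
    applying space-group symmetry operators and lattice translations to the
    asymmetric unit, computes solvent-accessible surface areas with a rolling
    probe, derives the standard geometric and physicochemical interface
    descriptors (interface area, non-bonded contacts, segments, core/non-polar/
    buried-atom fractions, residue propensity, local density, gap volume
    index, secondary-structure category), scores core-versus-surface sequence
    conservation from a multiple sequence alignment using a reduced ten-class
    amino-acid alphabet, applies dataset curation rules (resolution, size,
    redundancy, matched area controls), and provides comparative statistics
    and binary-classifier performance metrics. Includes seeded synthetic
    generators (toy dimers, toy crystals, alignments, descriptor tables) so
    every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, Biostrings
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'CrystalContacts-package.R'
    'conservation.R'
    'curation.R'
    'group-stats.R'
    'interface-props.R'
    'sasa.R'
    'spacegroups.R'
    'structure-io.R'
    'synthetic-data.R'
    'utils.R'
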