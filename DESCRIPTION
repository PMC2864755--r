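Package: designkit
Title: Fixed-Backbone Protein Design and Sequence-Ensemble Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for fixed-backbone computational
    protein design and for the statistical analysis of the sequence
    ensembles it produces.  Structures are modelled with a united-atom
    molecular-mechanics force field and a CASA implicit solvent
    (screened Coulomb plus atomic solvent-accessible-surface-area
    terms).  Side chains occupy discrete rotamers; singleton and
    pairwise energies over (position, type, rotamer) states are
    precomputed into an energy matrix, and sequences are optimised with
    a heuristic cycle algorithm against an Ala-X-Ala unfolded-state
    reference.  The analysis suite scores ensembles against multiple
    sequence alignments (BLOSUM-based similarity, reduced-alphabet
    positional entropy, mutual-information covariance), builds
    position-specific scoring matrices with pseudocounts, and runs an
    internal profile search with self-calibrated E-values.  A fixtures
    module generates ideal-geometry structures, planted-correlation
    alignments and decoy databases so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
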