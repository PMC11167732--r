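Package: cageflex
Title: Conformational State Analysis of Aromatic Cages in Reader Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating open, closed and collapsed states of
    aromatic cages (the Trp/Tyr/Phe pockets of methyl-lysine and
    methyl-arginine reader domains such as Tudor domains) from structural
    ensembles and molecular dynamics trajectories. Derives named reference
    states from a crystal-structure ensemble by threshold clustering of
    side-chain RMSD matrices, clusters trajectory frames by hierarchical
    agglomerative clustering on the same metric with Davies-Bouldin,
    pseudo-F and SSR/SST validity indices, tracks key-atom-pair distances
    and occupancy-grid pocket volumes inside a fixed envelope derived from
    open reference structures, and classifies sampled conformations against
    the references. Ships a synthetic cage generator with designable state
    geometry so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
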