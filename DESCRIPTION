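Package: pswdesign
Title: Design and Virtual Screening of Photoswitchable Azobenzene Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable re-implementation of a photopharmacology design
    platform. Mines parent ligands with curated binding-affinity data from a
    ChEMBL-schema SQLite snapshot, enumerates photoswitchable azobenzene
    analogs through azologization and azoextension transformation rules with
    trans/cis (E/Z) isomer pairs, prepares ligands and receptors for docking,
    and ranks designs with a docking-score-based isomeric-shift predictor
    (delta-pKi and fold-change) using Pareto multiobjective pose selection.
    Includes a deterministic mock docking engine and seeded fixture
    generators so the whole pipeline runs without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ChemmineR,
    DBI,
    RSQLite,
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel command line tools (obabel) for 3D ligand
    preparation; optional PLANTS docking engine.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
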