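Package: structrefine
Title: Confidence-Based Refinement of AI-Predicted Protein Structure Models
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-modeling curation of AI-predicted protein structures and
    their homology-model counterparts. Reads and writes PDB models carrying
    per-residue pLDDT confidence in the B-factor column, removes
    low-confidence regions by windowed pLDDT averaging with geometric pruning
    of detached segments, transplants small-molecule ligands from homology
    models into AI-predicted models via local binding-site superposition
    (Kabsch rigid-body fits with sequence-guided and structure-guided
    correspondences), and computes per-model quality statistics (pLDDT
    quartiles, Ramachandran dihedrals, secondary-structure fractions,
    pairwise model RMSD). Includes a deterministic synthetic-structure
    generator so the whole pipeline is testable without external data, plus
    sequence filtering and routing rules for planning large modeling runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
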