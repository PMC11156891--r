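# structrefine

Post-modeling curation of AI-predicted protein structures in R.

AI structure predictors (AlphaFold 2, OpenFold, ESMFold) emit full-length
models with a per-residue confidence score, the pLDDT (predicted local
distance difference test, 0–100, stored in the PDB B-factor column). Regions
predicted with low confidence — typically disordered linkers, termini or
transmembrane stretches — appear as unstructured loops that can block binding
sites and derail docking or dynamics studies. And because AI models contain
no ligands at all, the cofactors and small molecules present in homology
models of the same protein are invisible to any binding-site analysis.

`structrefine` implements the refinement layer that sits between structure
prediction and downstream analysis:

* **Confidence trimming.** For each residue *i* the pLDDT is averaged over a
  ±3-residue window, `w(i) = mean(pLDDT[i−3 … i+3])` (truncated at the chain
  termini); residues with `w(i) < 70` are removed. Retained residues form
  contiguous segments; the largest segment is the protein core, and a
  detached segment is kept only if its minimum inter-atomic distance to the
  core is ≤ 10 Å, or ≤ 5 Å to a segment that is itself within 10 Å of the
  core. Models with fewer than 10 surviving residues are dropped.
* **Ligand transplantation.** Small-molecule ligands are copied from a
  homology model (donor) into the AI model (acceptor) of the same protein.
  The donor chain best matching the acceptor sequence is selected (ties
  broken by ligand count); for each bound ligand, binding-site residues
  within 5/10/15 Å of the ligand are superposed onto the acceptor with two
  correspondence strategies — sequence-guided (BLOSUM62 global alignment
  plus iterative outlier rejection) and structure-guided (fragment-seeded
  mutual-nearest-neighbour Cα pairing). The lowest-RMSD fit places the
  ligand if RMSD ≤ 7 Å; placed ligands are screened for steric clashes and,
  after trimming, for 5 Å contact retention.
* **Superposition engine.** Exact closed-form Kabsch rigid-body fits
  (SVD of the cross-covariance, reflection-corrected, det R = +1).
* **Quality statistics.** pLDDT quartiles and the fraction of residues
  above 90 / above 70, Ramachandran (φ, ψ) dihedrals, a simple
  dihedral-region secondary-structure assignment, pairwise inter-model RMSD
  and a per-model CSV report.
* **Campaign planning.** Sequence filters (length 10–2700, no U/O/X/J/B/Z
  characters, protein-level existence, no fragments), per-tool routing
  rules (OpenFold ≤ 2000 residues; ESMFold API ≤ 400, ESMFold BioNeMo
  401–1024) and the accounting arithmetic of a proteome-scale run.
* **Synthetic fixtures.** A deterministic generator of ideal helices and
  strands (exact backbone torsions via natural-extension-of-reference-frame
  placement), trim fixtures with detached segments at exact distances, and
  donor/acceptor pairs with pseudo-ligands and geometric ground truths — so
  everything above is testable without downloading a single structure.

## Worked example

```r
library(structrefine)

# a 28-residue helix: two confident lobes (pLDDT 90) around a pLDDT-50 linker
fx <- make_trim_fixture(28, "two-lobe-low-linker", accession = "DEMO01")
tr <- trim_model(fx, trim_policy())
tr$report$removed_by_plddt
#> [1] 11 12 13 14 15 16 17 18
tr$model
#> <structure_model> DEMO01 (alphafold2)
#>   10 residues in 1 chain(s), 40 atoms, 0 ligand(s)
#>   pLDDT median 90.0 [90.0, 90.0]
```

The ±3-residue window averages fall below 70 exactly for residues 11–18
(e.g. residue 11 sees three 90s and four 50s: 470/7 ≈ 67.1), so the linker
is removed. On this straight helix the distal lobe then sits ~13 Å from the
core lobe and is pruned geometrically as well, leaving the 10-residue core.

```r
# donor/acceptor pair sharing one protein; the donor carries a pseudo-ligand
pair <- make_donor_pair(n = 24, seed = 42)
res <- transplant_all(pair$ai, pair$donor)
res$report
#>   het_id      outcome    best_rmsd winning_strategy chain_selected
#> 1    LIG transplanted 2.886739e-15      sequence@15              A
```

A self-transplant reproduces the donor pose to machine precision; the report
records the winning strategy/radius combination and the site RMSD that
passed the 7 Å gate.

A thin command-line front end (`exec/structrefine`) exposes the same
functionality as subcommands `fixtures`, `plan`, `trim`, `transplant`,
`stats` and `pipeline`.

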