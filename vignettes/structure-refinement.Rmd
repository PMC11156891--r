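---
title: "Confidence trimming, ligand transplantation and model QC with structrefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence trimming, ligand transplantation and model QC with structrefine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structrefine)
```

## The problem

Large-scale structure prediction of a proteome produces three kinds of
artifacts that downstream structural analysis has to cope with. First,
AI-predicted models always span the full sequence, including regions the
predictor had essentially no information about; these low-confidence
stretches appear as physically meaningless loops. Second, AI models carry
no ligands, while homology models built from experimentally solved
templates inherit cofactors and small molecules from those templates — so
the two model classes are not directly comparable around binding sites.
Third, once tens of thousands of models from several predictors exist,
per-model quality accounting (confidence summaries, dihedral sanity,
inter-model agreement) becomes part of the data product itself.

`structrefine` implements this curation layer: confidence-based trimming,
homology-to-AI ligand transplantation, and the associated statistics, all
on plain PDB files with pLDDT in the B-factor column.

## Confidence trimming

For a chain with per-residue confidences $p_1, \dots, p_n$ the windowed
average is

$$w_i = \frac{1}{|W_i|}\sum_{j \in W_i} p_j,\qquad
W_i = \{\,j : \max(1, i-h) \le j \le \min(n, i+h)\,\}$$

with half-width $h = 3$ residues. Residue $i$ is flagged for removal when
$w_i < 70$ (strictly; a window average of exactly 70 is retained). The
windowing deliberately spares isolated residues that only briefly dip below
the threshold, and the truncation at the termini means terminal residues are
judged by shorter windows rather than padded values.

Averages are computed **once, on the intact chain**. They are not
recomputed after removal: recomputation would expose new termini to
shorter, lower windows and erode the model cycle by cycle, and it would
make trimming non-idempotent on the retained set.

Retained residues form maximal contiguous segments. The *protein core* is
the segment with the most residues (ties: the earliest start). The notion
of "core" is an operational definition made here: the dominant retained
segment is what a structural biologist would recognize as the well-defined
body of the model. Every other segment is distance-tested with the
one-hop rule: it survives if its minimum inter-atomic distance to the core
is at most `core_distance` (10 Å), or if it is within `chain_distance`
(5 Å) of a segment that is itself within 10 Å of the core. The hop is
applied exactly once, not iterated to a fixed point — a literal reading of
the rule; chains of mutually-bridging fragments drifting away from the core
do not accumulate.

Distances use all heavy atoms rather than only Cα: spatial detachment is a
property of the chains' atoms, and the all-atom minimum is the stricter and
more reproducible choice. A `distance_atoms = "ca"` knob exists for
sensitivity analysis.

After pruning, a model with fewer than `min_residues` (10) surviving
residues is dropped entirely, and any ligand no longer within
`ligand_retention_distance` (5 Å) of a protein atom is discarded. The
survival filter is applied after **all** removals, matching the notion of
residues "remaining" in the refined model.

Trimming is pure deletion: no retained coordinate is ever modified, and the
whole procedure is deterministic.

### Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `window_halfwidth` | 3 | residues | pLDDT averaging half-window |
| `plddt_threshold` | 70 | pLDDT | strict removal threshold on the window average |
| `core_distance` | 10 | Å | max segment-to-core distance |
| `chain_distance` | 5 | Å | max distance to a bridging segment |
| `min_residues` | 10 | residues | survival threshold for the whole model |
| `ligand_retention_distance` | 5 | Å | post-trim ligand contact requirement |

## Ligand transplantation

The acceptor is an AI model, the donor a homology model of the same
protein. The procedure:

1. **Chain selection.** Each donor chain is scored by global sequence
   alignment (BLOSUM62, affine gaps: open 10, extend 0.5) against the
   acceptor sequence. Exact score ties are broken by the number of ligands
   assigned to the chain — a ligand belongs to the chain owning its nearest
   protein atom — and remaining ties by chain id. "Matched equally well" is
   read as exact arithmetic equality of alignment scores; near-ties resolve
   by score alone.
2. **Eligibility.** Only small-molecule HETATM groups qualify: nucleotides
   and amino acids recorded as HETATM are excluded, as are ligands with no
   atom within `donor_contact_distance` (5 Å) of the donor protein (no
   physical interaction to transfer). Waters were already dropped on read.
3. **Local site superposition.** For each eligible ligand, every
   combination of site radius (5, 10, 15 Å — a discrete realization of the
   5–15 Å band) and correspondence strategy is tried. The *sequence*
   strategy aligns the chains' sequences and pairs aligned Cα positions;
   the *structure* strategy is sequence-blind: all pairs of
   8-residue Cα fragments are Kabsch-fitted, the best seed transform is
   refined by mutual-nearest-neighbour pairing under a 5 Å cap, iterated to
   convergence. Both are then restricted to donor residues with an atom
   within the radius of the ligand and polished by iterative outlier
   rejection (drop pairs deviating more than 2 SD above the mean, refit,
   at most 5 cycles). These two strategies are this package's documented
   equivalents of the "align"-like and "super"-like alignment modes
   alternated in interactive molecular-graphics tools; every result records
   its `strategy@radius` label for provenance.
4. **Gate and placement.** The fit with the lowest site RMSD wins. RMSD is
   computed over Cα pairs — robust to side-chain rebuilding differences
   between modeling tools; an all-atom variant would punish rotamer noise,
   not site geometry. If the best RMSD is ≤ `rmsd_max` (7 Å) the ligand is
   mapped into the acceptor frame with the inverse transform; otherwise the
   incorporation is omitted. Each ligand gets its own best transform —
   sites move semi-independently between models, and a single global fit
   would misplace ligands in hinged or partially remodeled regions.
5. **Clash screen.** If an external energy-minimization hook is configured
   (a shell command template receiving `{in}`/`{out}` PDB paths) it runs on
   the complex first; then any ligand with a heavy atom closer than
   `clash_distance` to a protein heavy atom is deleted. The 2.0 Å default
   is a deliberate, documented choice: it is well inside the shortest
   plausible non-bonded contact (~2.4 Å for an H-bonded O···O), so it only
   fires on genuine interpenetration. Energy minimization itself is out of
   scope — it is force-field work for an external engine, and the hook
   preserves the run order (minimize, then screen).

Acceptor protein coordinates are never modified by transplantation; ligands
are purely added. Lowering `rmsd_max` can only shrink the set of
transplanted ligands.

## Superposition

`kabsch_fit()` is the closed-form least-squares rigid fit: SVD of the
cross-covariance of the centered point sets, with the smallest singular
direction sign-flipped when needed so the rotation is proper
(det R = +1, never a reflection). Collinear point sets leave a rotation
degree of freedom undetermined and are rejected (second singular value
below 1e-8 of the largest), as are sets of fewer than 3 points. Outlier
rejection in `refine_fit()` uses a deviation floor of 1e-6 Å so that an
essentially exact fit does not reject pairs on numerical noise.

## Quality statistics

* pLDDT quartiles use linear interpolation between order statistics
  (R's default quantile type 7); the convention is stated here because
  different conventions shift quartiles of short models noticeably.
* "Above 90" and "above 70" are strict inequalities: a residue at exactly
  90 counts as *not* above 90.
* φ/ψ dihedrals follow the IUPAC sign convention; terminal residues lack
  the angle that points off the chain, and residues are treated as
  neighbours only when consecutively numbered in the same chain, so
  trim-induced gaps correctly break the dihedral chain.
* The secondary-structure assignment is a deliberately simple
  dihedral-region method — helix for φ ∈ (−100, −30), ψ ∈ (−80, −5);
  strand for φ ∈ (−180, −100) with ψ ∈ (90, 180] ∪ (−180, −170); coil
  otherwise, with runs shorter than 3 reassigned to coil. It is an
  approximate classifier for reporting, not DSSP: no hydrogen-bond
  geometry is evaluated. Fractions are computed over residues with both
  angles defined.
* Pairwise model RMSD corresponds residues by residue number (homology
  models may cover a subsequence), fits on Cα, and marks pairs with fewer
  than 3 common residues as undefined.
* Homology-model z-scores are opaque pass-through metadata: they are
  produced by the external modeling engine's own structural comparison and
  are never computed here.

## The synthetic generator

All test inputs are generated, never downloaded. Backbones are built by
natural-extension-of-reference-frame placement from canonical bond lengths
and angles, so a chain constructed with φ = −57°, ψ = −47° *measures* those
torsions back (at PDB coordinate precision, ~0.05°) and exhibits the
canonical ~1.5 Å rise and ~3.8 Å consecutive Cα distances of an α-helix.
Trim fixtures translate residue ranges along a direction and solve the
translation magnitude numerically (uniroot on the brute-force minimum
distance) so detached segments sit at *exactly* the requested gap. Donor
fixtures place rigid pseudo-ligand atom clusters near anchor residues,
resampling deterministically until the cluster is 2.5–5 Å clear of the
protein — inside the donor-contact band, outside the clash band — and
return ground-truth acceptor-frame ligand coordinates computed by direct
geometry, independent of the transplant code they are used to test.

What the generator does **not** emulate: side chains (models are
backbone-only poly-alanine unless a sequence is requested), realistic
B-factor noise, alternate conformations, insertion codes, or chemically
meaningful ligands (pseudo-ligands are geometry only). Passing tests
therefore demonstrate the correctness of the geometric and statistical
machinery, not robustness to the full messiness of real depositions —
though the PDB reader does handle HETATM categorization, waters, altLocs
and multi-model files.

## Problem sizes and determinism

The shipped tests and the acceptance script run on fixtures of 10–44
residues, 1000 randomized pruning fixtures against a brute-force oracle,
and 10,000-transform Monte-Carlo checks of fit optimality — sizes chosen so
the full suite exercises every code path in well under a minute on one CPU
while keeping the oracles exhaustive. Every stochastic fixture is seeded;
identical inputs yield byte-identical pipeline outputs, which the test
suite asserts by re-running the pipeline and comparing files.

## Known limitations

* Multi-chain AI models are rejected on read; the AI predictors targeted
  here emit single-chain monomers, and the trimming semantics for
  inter-chain cores are deliberately not invented.
* The one-hop bridging rule and the largest-segment core definition are
  faithful operationalizations of a procedure described in prose; other
  readings (iterated bridging, density-based cores) would retain slightly
  different fragment sets.
* pLDDT scale detection treats a profile with maximum ≤ 1.0 as fractional
  and rescales ×100. A genuine percent-scale model whose every residue is
  below 1 pLDDT would be misread — such a model is vanishingly unlikely
  and would be worthless anyway.
* Sequence-identical chains make alignment gap placement ambiguous
  (any gap position scores equally in a homopolymer); the structure-guided
  strategy exists precisely for such cases.
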