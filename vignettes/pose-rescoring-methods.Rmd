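---
title: "Methods: machine-learned pose rescoring and docking-power evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: machine-learned pose rescoring and docking-power evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posepower)
```

## The problem

Docking programs generate ranked candidate placements ("poses") of a ligand
in a receptor pocket. A pose is *near-native* when its heavy-atom RMSD to the
crystallographic ligand is below 2.0 Å (strictly: an RMSD of exactly 2.0 Å is
a decoy). *Docking power* is a scoring function's ability to put a
near-native pose at the top of each complex's ranked list. `posepower`
implements the full workflow for building and judging machine-learned
rescoring functions for this task: featurization of protein-ligand poses,
symmetry-corrected RMSD labeling, leakage-aware data splitting,
gradient-boosted classification, and the evaluation statistics used by
docking-power benchmarks.

## Labels: symmetry-corrected RMSD

Chemically equivalent atoms (the two ortho carbons of a phenyl ring, the two
carboxylate oxygens) make the naive coordinate-wise RMSD overestimate the
deviation of a pose. `symmetry_rmsd()` therefore minimizes the RMSD over all
automorphisms of the molecular graph, enumerated as element-colored VF2
isomorphisms between the heavy-atom bond graphs of pose and reference. Three
numerical choices matter:

* **No superposition.** Docked and crystal poses share the receptor frame, so
  RMSD is computed in place. Rigidly translating a pose by a vector *t*
  changes its RMSD by exactly |*t*|, which the tests assert.
* **Bond orders are ignored for the coloring** (element + connectivity only),
  making the correction robust to dialect-dependent bond-order perception in
  SDF/MOL2 files. A consequence, verified in the tests, is that a benzene and
  a cyclohexane pose are comparable graphs.
* **Enumeration cap.** Pathologically symmetric molecules could have huge
  automorphism groups; above 10 000 mappings the implementation falls back to
  a Hungarian assignment of atoms within element classes (a lower-bound
  heuristic) and warns. None of the built-in ligands comes near the cap.

For molecules with up to 8 heavy atoms an exhaustive permutation oracle
(every element- and adjacency-preserving permutation) reproduces the VF2
result exactly; this is part of the test suite.

## Features

Four interaction families and one control are available, concatenated by
`assemble_features()` under a fixed schema:

* **ELEM (36)** — contact counts between the 4 protein elements (C, N, O, S)
  and 9 ligand elements (C, N, O, S, P, F, Cl, Br, I) within 6.0 Å.
  The distance comparison is inclusive (a pair at exactly 6.0 Å counts):
  conventions differ between implementations at the boundary, and an
  inclusive rule is deterministic and matches the common choice.
* **ECIF (1562)** — the same counting over connectivity-typed atoms. Each
  atom is keyed as `Element;Valence;HeavyNeighbors;AttachedH;IsAromatic;
  IsInRing`. 22 protein types x 71 ligand types give 1562 features.
* **Vina terms (5)** — the steric and interaction terms of the AutoDock Vina
  functional form (gauss1, gauss2, repulsion, hydrophobic, hydrogen bond) on
  the surface distance d = r − (R_i + R_j), summed over pairs with r ≤ 8 Å.
  Hydrophobic carbons are carbons with no bonded N/O/S; donors are N/O
  carrying a hydrogen; acceptors any N/O. These forms are validated against
  a per-pair formula oracle to 1e-9; parity with a particular Vina build is
  not claimed (the published terms are re-implemented, not wrapped).
* **Rank (1)** — the 1-based rank emitted by the docking program. Crystal
  poses and pooled multi-program sets have no rank; the feature is `NA`
  there, and a model trained with the rank family refuses to score such rows
  rather than imputing silently.
* **Ligand-only control (20)** — element counts, a 1-Å-binned histogram of
  intramolecular distances, and the radius of gyration. By construction it
  sees no receptor information; it exists to verify that interaction models
  actually learn interactions (see the recovery experiment below).

### Atom-typing conventions

Attached hydrogens are never read from the input (all structures are
heavy-atom only); they come from implicit-valence completion. For ligands,
the per-atom bond-order sum uses order 1.5 for aromatic bonds at carbon and
at 2-connected nitrogen (pyridine-type), and 1.0 at oxygen, sulfur and
3-connected nitrogen, which donate a lone pair to the ring. This reproduces
the canonical valences of benzene, pyridine, furan, thiophene and
N-substituted azoles from either aromatic-flagged or kekulized input. One
known limitation: a pyrrole-type N–H nitrogen is indistinguishable from a
pyridine-type nitrogen on a heavy-atom graph with aromatic flags only, and is
typed as pyridine-like; the built-in ligand library avoids such atoms.

For protein atoms, typing goes through hand-curated residue templates
(`amino_acid_templates()`): every heavy atom of the 20 canonical amino acids
in mid-chain peptide context, with known hydrogen counts and physiological
protonation (Lys+, Arg+, Asp−, Glu−). The atom's valence is its standard
valence plus formal charge, which is exact for amino-acid chemistry.
`derive_protein_type_vocabulary()` types every template atom — including the
histidine tautomers/imidazolium and both kekulizations of the
resonance-delocalized arginine guanidinium, whose single kekulized form would
arbitrarily break a chemical symmetry — and yields exactly 22 distinct
types, the published width of the protein side of the ECIF schema.

The 71-type ligand vocabulary cannot be re-derived without the external
ligand corpus it originally came from, so the package ships a synthetic
reconstruction at the published width
(`inst/extdata/ecif_ligand_types_synthetic.txt`): a systematic enumeration of
chemically realizable connectivity types over the nine-element alphabet.
Every type that the package's own typing rule can produce on the built-in
library is a member (tested); types absent from data simply yield always-zero
columns, which the variance filter removes before training. Counts against a
different 71-type list would populate different columns but identical
geometry, so conclusions from the synthetic studies do not depend on the
reconstruction matching the original list entry-by-entry.

## Splits

All partitioning is by target (complex), never by pose. Three schemes:

* `random_split()` — 4:1 train/test, repeated 10 times by default;
  test size is `round(n/5)`.
* `refined_core_split()` — a fixed held-out core set.
* `clustered_cv_split()` — threefold clustered cross-validation. Two
  complexes are *linked* when protein sequence similarity ≥ 0.5, or ≥ 0.3
  while ligand Tanimoto similarity ≥ 0.9. Connected components of the
  linkage graph are assigned whole to folds (greedy largest-first
  balancing), which *guarantees* that no cross-fold pair satisfies the
  linkage predicate — a property a flat-threshold clustering would not give.
  The price is balance: one dominant component can skew fold sizes, which
  triggers a warning with the achieved sizes. On sparse random similarity
  structures fold sizes stay within ±25% of n/k (tested).

Ligand similarity is the Tanimoto coefficient over a path-based topological
fingerprint (simple bond paths of 1–7 bonds, canonicalized and hashed onto
2048 bits). Sequence similarity is a global alignment with match score 1 and
no mismatch/gap penalties — whose score equals the
longest-common-subsequence length — normalized by the longer sequence. The
normalization is a package choice (the convention in the source protocol is
not stated); dividing by max length bounds the value in [0,1] and penalizes
length mismatch.

## Model

`tune_and_train()` follows a fixed protocol:

1. **Variance filter**: training-set features with variance < 0.01 are
   dropped (a feature at exactly 0.01 is kept). With sparse ECIF counts this
   typically removes most of the 1562 columns.
2. **Standardization** to zero mean, unit sd, with statistics from training
   rows only. The no-leakage property is asserted in the tests.
3. **Hyperparameter search** over a documented space (max_depth 3–10,
   learning rate 10^[−3,−0.5], 100–1000 rounds, subsample and
   colsample_bytree 0.5–1, min_child_weight 1–10, gamma 0–5, lambda
   10^[−2,1]), scored by grouped fivefold cross-validated AUROC: CV folds
   are partitions of complexes, so poses of one complex never straddle a
   fold. The search is a seeded random search with a default budget of 60
   evaluations; the original protocol used a Tree-structured Parzen
   estimator, for which no R implementation is available here — with the
   same budget, objective and fixed seed, random search is a reproducible
   stand-in and every evaluation is logged in the returned tuning history.
4. **Refit** on all training rows with the best configuration.

Seeds are fixed at 2399 (booster, single-threaded) and 123 (tuner), making
the whole pipeline run-to-run identical — the tests compare serialized
boosters byte for byte. An RMSD regressor (`train_regressor()`) shares the
protocol with an RMSE objective and predictions clipped at 0 Å. No class
reweighting is applied (none is used in the reference protocol).

## Evaluation

`scored_poses()` builds the evaluation table; by default crystal poses are
removed from test sets, since real rescoring only ever sees generated poses.
Metrics:

* **inter-AUROC / inter-Rs** — pooled over all poses of all complexes;
  AUROC is the tie-aware Mann–Whitney estimator (the identity is asserted
  against explicit pair counting), Rs the Spearman correlation between score
  and RMSD. Scores are oriented "higher = better pose", so a good method has
  strongly *negative* Rs; that sign convention is reported as-is.
* **intra-AUROC / intra-Rs** — computed within each complex, then averaged.
  Complexes where a statistic is undefined (single class; fewer than 3 poses
  or no variation) are skipped and counted, not zero-filled: zero-filling
  would conflate "cannot be evaluated" with "performs at chance".
* **SR1 / SR3** — fraction of complexes with a near-native pose among the
  top-k by score. Score ties break by docking rank, then input order, so
  success rates are deterministic. SR1 ≤ SR2 ≤ SR3 ≤ ceiling always holds,
  where the **ceiling** is the fraction of complexes with any near-native
  pose at all.
* **Binding funnel** — mean per-complex Spearman Rs restricted to RMSD
  windows [0–2], [0–3], …, [0–10] Å (1 Å steps, configurable).
* **Ensemble pooling** — all poses of one ligand across several receptor
  structures are treated as a single set; each pose keeps its own-receptor
  RMSD, so success is judged on the selected pose's own geometry.
* **Uncertainty and comparison** — bootstrap over complexes (1000
  replicates, seeded) for any statistic; two-sided Wilcoxon signed-rank on
  paired per-complex values for method comparisons, significant at p < 0.05,
  with p = 1 reported in the degenerate all-zero-differences case.

All ranking metrics are invariant under strictly monotone transforms of the
scores (property-tested), so classical scoring functions can be compared by
supplying their scores in the `evaluate` stage with the orientation declared.

## The synthetic study system

No deposited structures are used anywhere. `make_pocket()` samples whole
residues from the templates and places them on a bowl-shaped shell (radius
5–8.5 Å, directions biased below the equator) around the origin, growing
each residue's atoms along its bond graph; pockets have 30–80 heavy atoms,
all of which receive a valid ECIF protein type. The reference ligand — drawn
from a 20-molecule built-in library spanning the nine-element alphabet — is
centred at the origin inside the bowl. `make_pose_ensemble()` perturbs it
rigidly (rotation + translation) with a constant 0.05 Å per-atom jitter,
producing up to 20 poses whose realized symmetry-corrected RMSDs span
roughly [0, 8] Å; perturbations are rescaled until each pose lands on its
intended side of the 2.0 Å cutoff, so the positive fraction is controlled to
within ±5%. Decoy translations are biased out of the bowl, so near-native
poses genuinely make more receptor contacts: interaction features carry the
label signal. Because conformational jitter is constant across poses,
ligand-only geometry carries none of it. Docking ranks are assigned by a
noisy function of RMSD (Spearman ≈ 0.3–0.95 against RMSD in tests):
informative, but imperfect.

This is the basis of the **recovery experiment** (`planted_signal_dataset()`,
200 complexes, 20 poses each, fixed seeds; a fifth of the targets held out):
an ECIF+Vina model reaches held-out intra-AUROC ≥ 0.85 while the ligand-only
control stays at 0.5 ± 0.1. Passing it shows the pipeline learns
interactions and not ligand identity; it does *not* show performance on real
docking data — the generator has no induced fit, no electrostatics, no
realistic pose energetics, and its decoy geometry is simpler than a docking
program's.

## Problem sizes and runtime choices

The shipped tests run the recovery experiment at the study scale
(200 complexes x 20 poses) with a search budget of 4 evaluations — ample for
this planted signal, and chosen so the whole suite completes in a few
minutes on one CPU. Unit and property tests use 10–40 complexes. The
60-evaluation default of `tune_and_train()` is what a real training run
should use. The acceptance script (`scripts/acceptance.R`) re-runs the
recovery experiment and the docking-power evaluation from scratch at the
same sizes under a caller-supplied seed.

## Known limitations

* The ligand-type vocabulary is a synthetic reconstruction (see above).
* Pyrrole-type N–H typing on heavy-atom-only aromatic input (see above).
* The MOL2 reader covers the TRIPOS ATOM/BOND dialect used by docking tools;
  exotic records (substructures, charges) are ignored.
* No protonation, charge assignment, structure repair or receptor alignment
  is performed; coordinates are trusted to share one frame.
* Probabilities from the classifier are not calibrated; only their order is
  used by the evaluation metrics.
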