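# posepower

Machine-learned rescoring of protein–ligand binding poses, and the full
docking-power evaluation suite for judging it.

## The problem

A docking program proposes up to 20 candidate placements (*poses*) of a
ligand in a receptor pocket, ranked by its internal score. Those ranks are
often wrong: the *near-native* pose — heavy-atom RMSD to the crystal ligand
below 2.0 Å — is frequently buried in the list. Rescoring replaces the
docking score with a learned one. `posepower` is for computational chemists
who want to build such rescoring functions and, just as importantly, measure
their *docking power* honestly: per-target success rates against the
attainable ceiling, pooled and per-target AUROC and Spearman statistics,
binding-funnel profiles, bootstrap uncertainty, and similarity-clustered
splits that keep look-alike targets out of the test set.

## What is inside

* **Structure I/O** — receptor PDB (heavy ATOM records, altloc resolved),
  ligand SDF/MOL2 with bond graphs; pose sets assembled with docking ranks,
  optional crystal-pose inclusion (training convention) and cross-native
  pose exclusion (cross-docking convention).
* **Labels** — symmetry-corrected RMSD: the minimum over all element-colored
  graph automorphisms of the in-place heavy-atom RMSD,
  `label = positive ⇔ RMSD < 2.0 Å` (strict).
* **Features** — ELEM element-pair contact counts (4 × 9 = 36, cutoff
  6.0 Å); ECIF connectivity-typed pair counts over
  `Element;Valence;HeavyNeighbors;AttachedH;IsAromatic;IsInRing` atom types
  (22 protein × 71 ligand = 1562); the five AutoDock-Vina-style terms
  (gauss1, gauss2, repulsion, hydrophobic, H-bond) on the surface distance
  d = r − (R_i + R_j); the docking rank; and a ligand-only control
  descriptor used to prove that models learn interactions, not ligands.
* **Splits** — random 4:1 (×10), refined-core, and threefold clustered CV:
  complexes linked at protein sequence similarity ≥ 0.5 (or ≥ 0.3 when
  ligand Tanimoto ≥ 0.9) are assigned to folds as whole connected
  components, so no similar pair ever straddles a fold.
* **Model** — XGBoost classifier (or RMSD regressor): variance filter
  (< 0.01), standardization fitted on training rows only, hyperparameter
  search scored by grouped fivefold CV-AUROC, fixed seeds 2399/123 for
  byte-identical reruns.
* **Evaluation** — SR1/SR3 with deterministic tie-breaking, success-rate
  ceiling, inter/intra AUROC and Rs, binding-funnel analysis over RMSD
  windows [0–2]…[0–10] Å, ensemble pooling across receptor structures,
  1000-fold bootstrap over complexes, paired Wilcoxon signed-rank tests.
* **Synthetic generator** — deterministic pocket/pose/label generator so the
  entire pipeline is testable at desk scale with no external data.

See `vignettes/pose-rescoring-methods.Rmd` for the conventions, the design
choices and their rationale, and known limitations.

## Worked example

Train an ECIF+Vina rescoring model on synthetic complexes and evaluate its
docking power on held-out targets:

```r
library(posepower)

ds <- planted_signal_dataset(n_complexes = 30, seed = 42)   # 30 complexes x 20 poses
features <- assemble_features(ds$pose_sets, families = c("ecif", "vina"))

held_out <- sprintf("cx%04d", 25:30)                        # target-level split
model <- tune_and_train(features[!features$complex_id %in% held_out, ],
                        max_evals = 8)
print(model)
#> pose_model (classify): 211 features kept, best CV score 0.9016

test_rows <- features[features$complex_id %in% held_out, ]
sets <- scored_poses(test_rows, predict(model, test_rows), drop_crystal = FALSE)
print(evaluate_report(sets, n_boot = 1000, seed = 1))
#> eval_report: 6 complexes, 120 poses
#>   inter AUROC 0.903, inter Rs -0.663 | intra AUROC 0.893, intra Rs -0.634
#>   sr1 = 0.833 (bootstrap 0.834 +/- 0.150)
#>   sr3 = 1.000 (bootstrap 1.000 +/- 0.000)
#>   ceiling = 1.000
```

Reading the numbers: of the 1567 concatenated features, 211 survive the
variance filter on this training set. On the six held-out complexes the model
scores a near-native pose on top (`sr1`) for 5/6 targets; every target is
solved within the top three (`sr3 = 1`), and every target has at least one
near-native pose available (`ceiling = 1`), so the rescorer — not the pose
generator — is what is being measured. The pooled AUROC of 0.90 and the
strongly negative score–RMSD Spearman correlation say the score orders poses
by geometric quality well beyond the top ranks.

The same pipeline runs from the shell:

```sh
inst/exec/posepower simulate  --out sim --n 30 --seed 42
inst/exec/posepower featurize --metadata sim/metadata.csv --out feat.csv --families ecif,vina
inst/exec/posepower train     --table feat.csv --out model.rds --max-evals 8
inst/exec/posepower rescore   --model model.rds --table feat.csv --out scored.csv
inst/exec/posepower evaluate  --scored scored.csv --out report.json
```

`evaluate` accepts any scored-pose table keyed by (complex_id, pose_id), so
classical scoring functions can be benchmarked by supplying their own score
column (higher = better).

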