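Package: posepower
Title: Machine-Learned Rescoring and Docking-Power Evaluation of
    Protein-Ligand Binding Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating machine-learning scoring
    functions that classify docked protein-ligand binding poses as
    near-native or decoy. Provides parsers for receptor (PDB) and ligand
    (SDF/MOL2) structures, symmetry-corrected heavy-atom RMSD labeling
    against a crystal reference, interaction featurization (element-pair
    counts, connectivity-typed ECIF pair counts, AutoDock-Vina-style
    empirical energy terms, docking-rank and ligand-only control
    features), target-level data splitting including clustered
    cross-validation constrained by protein sequence and ligand
    fingerprint similarity, gradient-boosted classifier training with
    grouped cross-validated hyperparameter search, and the full
    docking-power evaluation suite (inter/intra AUROC and Spearman
    correlations, top-k success rates with ceiling, binding-funnel
    analysis, ensemble pooling, bootstrap uncertainty, and paired
    significance tests). A synthetic complex generator makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    arrow,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
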