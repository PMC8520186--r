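# ELEM / ECIF / Vina / rank / ligand-control featurization

test_that("schema constants: 36 ELEM, 1562 ECIF, 22 protein and 71 ligand types", {
  expect_length(ecif_protein_vocabulary(), 22)
  expect_length(ecif_ligand_vocabulary(), 71)
  rc <- random_complex(1)
  expect_length(elem_featurize(rc$receptor, rc$ligand), 36)
  expect_length(ecif_featurize(rc$receptor, rc$ligand), 1562)
  sch <- feature_schema(c("ecif", "vina", "rank"))
  expect_length(sch$names, 1562 + 5 + 1)
  expect_length(feature_schema("elem")$names, 36)
})

test_that("shipped protein vocabulary equals the template-derived set", {
  expect_identical(ecif_protein_vocabulary(),
                   derive_protein_type_vocabulary())
})

test_that("vocabulary derivation behaves like a set", {
  tpls <- amino_acid_templates()
  full <- derive_protein_type_vocabulary(tpls)
  gly <- derive_protein_type_vocabulary(tpls["GLY"])
  expect_true(all(gly %in% full))
  expect_lt(length(gly), length(full))
  expect_identical(derive_protein_type_vocabulary(c(tpls, tpls["GLY"])), full)
})

test_that("ECIF atom types match forced and oracle-derived examples", {
  # methane: a single carbon with four implicit hydrogens
  expect_equal(ecif_atom_type(point_ligand("C")), "C;4;0;4;0;0")
  benz <- ligand_library()$benzene
  expect_equal(unique(ecif_atom_type(benz)), "C;4;2;1;1;1")
  # alanine backbone carbonyl carbon, from the template annotations
  ann <- protein_atom_annotations()
  expect_equal(ann$ecif_type[ann$resname == "ALA" & ann$atom_name == "C"],
               "C;4;3;0;0;0")
})

test_that("single-pair ELEM counting and the cutoff boundary", {
  rec <- toy_receptor(data.frame(element = "C", x = 0, y = 0, z = 0))
  v <- elem_featurize(rec, point_ligand("C", 3, 0, 0))
  expect_equal(unname(v["ELEM__C__C"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(sum(elem_featurize(rec, point_ligand("C", 6.5, 0, 0))), 0)
  expect_equal(sum(elem_featurize(rec, point_ligand("C", 6.0, 0, 0))), 1)  # inclusive
  # far ligand: ECIF zero vector too
  expect_equal(sum(ecif_featurize(rec, point_ligand("C", 30, 0, 0))), 0)
})

test_that("pair-count featurizers equal brute-force double-loop oracles", {
  for (seed in 1:100) {
    rc <- random_complex(seed)
    expect_equal(unname(elem_featurize(rc$receptor, rc$ligand)),
                 elem_oracle(rc$receptor, rc$ligand))
    expect_equal(unname(ecif_featurize(rc$receptor, rc$ligand)),
                 ecif_oracle(rc$receptor, rc$ligand))
    expect_equal(unname(vina_terms(rc$receptor, rc$ligand)),
                 vina_oracle(rc$receptor, rc$ligand), tolerance = 1e-9)
  }
})

test_that("vina terms at touching distance: gauss1 = 1, repulsion = 0", {
  rec <- toy_receptor(data.frame(element = "C", x = 0, y = 0, z = 0))
  v <- vina_terms(rec, point_ligand("C", 3.8, 0, 0))  # r = R_C + R_C
  expect_equal(unname(v["VINA__gauss1"]), 1.0)
  expect_equal(unname(v["VINA__repulsion"]), 0.0)
  far <- vina_terms(rec, point_ligand("C", 8.5, 0, 0))
  expect_equal(unname(far), rep(0, 5))
})

test_that("interaction features are invariant to atom order and rigid motion", {
  rc <- random_complex(7, lig = ligand_library()$methyl_phosphate)
  base <- c(elem_featurize(rc$receptor, rc$ligand),
            ecif_featurize(rc$receptor, rc$ligand),
            vina_terms(rc$receptor, rc$ligand))
  # shuffle receptor atom order
  set.seed(8)
  idx <- sample(nrow(rc$receptor$atoms))
  rec2 <- protein_structure(rc$receptor$atoms[idx, ])
  shuf <- c(elem_featurize(rec2, rc$ligand), ecif_featurize(rec2, rc$ligand),
            vina_terms(rec2, rc$ligand))
  expect_equal(shuf, base, tolerance = 1e-12)
  # joint rigid transform of receptor and pose
  R <- rotation_by_angle(1.1)
  t <- c(4, -2, 7)
  ratoms <- rc$receptor$atoms
  xyz <- as.matrix(ratoms[, c("x", "y", "z")]) %*% t(R)
  ratoms$x <- xyz[, 1] + t[1]; ratoms$y <- xyz[, 2] + t[2]
  ratoms$z <- xyz[, 3] + t[3]
  moved <- c(elem_featurize(protein_structure(ratoms), transform_mol(rc$ligand, R, t)),
             ecif_featurize(protein_structure(ratoms), transform_mol(rc$ligand, R, t)),
             vina_terms(protein_structure(ratoms), transform_mol(rc$ligand, R, t)))
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("enlarging the cutoff never decreases a contact count", {
  for (seed in 1:20) {
    rc <- random_complex(seed, n_rec = 30)
    e4 <- elem_featurize(rc$receptor, rc$ligand, cutoff = 4)
    e6 <- elem_featurize(rc$receptor, rc$ligand, cutoff = 6)
    e9 <- elem_featurize(rc$receptor, rc$ligand, cutoff = 9)
    expect_true(all(e6 >= e4) && all(e9 >= e6))
    c4 <- ecif_featurize(rc$receptor, rc$ligand, cutoff = 4)
    c6 <- ecif_featurize(rc$receptor, rc$ligand, cutoff = 6)
    expect_true(all(c6 >= c4))
  }
})

test_that("rank feature: docked rank or missing for crystal poses", {
  expect_equal(unname(rank_feature(list(dock_rank = 1L))), 1)
  expect_equal(unname(rank_feature(list(dock_rank = 17L))), 17)
  expect_true(is.na(rank_feature(list(dock_rank = NA_integer_,
                                      is_crystal = TRUE))))
})

test_that("ligand control is receptor-independent but conformation-sensitive", {
  lig <- ligand_library()$butane
  a <- ligand_control_featurize(lig)
  expect_length(a, 20)
  expect_identical(a, ligand_control_featurize(lig))  # no receptor anywhere
  # rigid motion leaves it unchanged; stretching does not
  moved <- transform_mol(lig, rotation_by_angle(0.9), c(10, 0, 0))
  expect_equal(ligand_control_featurize(moved), a, tolerance = 1e-9)
  stretched <- lig
  stretched$atoms$x <- stretched$atoms$x * 1.6
  expect_false(isTRUE(all.equal(ligand_control_featurize(stretched), a)))
  single <- ligand_control_featurize(point_ligand("C"))
  expect_equal(sum(single[grep("dhist", names(single))]), 0)
})

test_that("feature assembly concatenates blocks and applies the rank policy", {
  sd <- shared_dataset()
  ft <- sd$ft
  expect_equal(ncol(ft) - 6, 36 + 5 + 1)  # elem + vina + rank blocks
  expect_true(all(c("complex_id", "pose_id", "rmsd", "label") %in% names(ft)))
  expect_true(all(ft$RANK__dock_rank[!ft$is_crystal] >= 1))
  expect_error(assemble_features(sd$ds$pose_sets[[1]], families = character(0)),
               "empty family")
  # a set without ranks refuses the rank family
  ps <- sd$ds$pose_sets[[1]]
  for (k in seq_along(ps$poses)) ps$poses[[k]]$dock_rank <- NA_integer_
  expect_error(assemble_features(ps, families = c("elem", "rank")),
               "rank-free")
})
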