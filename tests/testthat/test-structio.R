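# PDB/SDF/MOL2 parsing and pose-set assembly

pdb_line <- function(serial, name, resname, chain, resno, x, y, z, element,
                     alt = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, element)
}

write_gly_tripeptide <- function(path, with_h = FALSE, altloc_dup = FALSE) {
  lines <- character(0)
  serial <- 0
  for (res in 1:3) {
    for (atom in list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))) {
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, atom[1], "GLY", "A", res,
                                 res * 3 + serial * 0.1, 0, 0, atom[2]))
    }
    if (with_h) {
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, "H", "GLY", "A", res,
                                 res * 3, 1, 1, "H"))
    }
  }
  if (altloc_dup) {
    lines <- c(lines,
               pdb_line(serial + 1, "CA", "GLY", "A", 3, 9.0, 2, 0, "C", "B"))
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("PDB parsing keeps heavy ATOM records and drops hydrogens", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_gly_tripeptide(f, with_h = TRUE)
  prot <- read_protein(f)
  expect_equal(nrow(prot$atoms), 12)  # 4 heavy atoms x 3 residues, no H
  expect_false(any(prot$atoms$element == "H"))
  expect_equal(unname(prot$chains["A"]), "GGG")
})

test_that("altloc duplicates keep the first-listed copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_gly_tripeptide(f, altloc_dup = TRUE)
  prot <- read_protein(f)
  ca3 <- prot$atoms[prot$atoms$resno == 3 & prot$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca3), 1)
  expect_false(isTRUE(all.equal(ca3$x, 9.0)))  # first-listed copy retained
})

test_that("read_protein errors on missing and empty input", {
  expect_error(read_protein("no_such_file.pdb"), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_protein(f))
})

test_that("SDF parsing: benzene flags, multi-record order, ethane", {
  lib <- ligand_library()
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(lib$benzene, lib$ethane, lib$butane), f)
  mols <- read_ligand(f)
  expect_length(mols, 3)
  expect_equal(vapply(mols, n_atoms, integer(1)), c(6L, 2L, 4L))
  benz <- mols[[1]]
  expect_equal(nrow(benz$bonds), 6)
  expect_true(all(benz$atoms$aromatic))
  expect_true(all(benz$atoms$in_ring))
  eth <- mols[[2]]
  expect_equal(nrow(eth$bonds), 1)
  expect_false(any(eth$atoms$in_ring))
  expect_false(any(eth$atoms$aromatic))
})

test_that("SDF round trip preserves elements, coordinates and topology", {
  lib <- ligand_library()
  for (mol in lib[c("acetate", "methyl_phosphate", "thiophene", "toluene")]) {
    f <- withr::local_tempfile(fileext = ".sdf")
    write_sdf(mol, f)
    back <- read_ligand(f)[[1]]
    expect_equal(back$atoms$element, mol$atoms$element)
    expect_equal(mol_coords(back), mol_coords(mol), tolerance = 1e-3)
    expect_equal(back$atoms$charge, mol$atoms$charge)
    expect_equal(back$bonds[, c("i", "j")], mol$bonds[, c("i", "j")])
    expect_equal(back$bonds$aromatic, mol$bonds$aromatic)
  }
})

test_that("MOL2 parsing maps SYBYL types and aromatic bonds", {
  f <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "pyr", " 6 6 0 0 0", "SMALL", "NO_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 N1  1.380  0.000 0.0 N.ar 1 PYR 0.0",
    "  2 C2  0.690  1.195 0.0 C.ar 1 PYR 0.0",
    "  3 C3 -0.690  1.195 0.0 C.ar 1 PYR 0.0",
    "  4 C4 -1.380  0.000 0.0 C.ar 1 PYR 0.0",
    "  5 C5 -0.690 -1.195 0.0 C.ar 1 PYR 0.0",
    "  6 C6  0.690 -1.195 0.0 C.ar 1 PYR 0.0",
    "@<TRIPOS>BOND",
    " 1 1 2 ar", " 2 2 3 ar", " 3 3 4 ar", " 4 4 5 ar", " 5 5 6 ar",
    " 6 6 1 ar"), f)
  mol <- read_ligand(f)[[1]]
  expect_equal(mol$atoms$element, c("N", rep("C", 5)))
  expect_true(all(mol$bonds$aromatic))
  expect_equal(ecif_atom_type(mol, 1), "N;3;2;0;1;1")
})

test_that("missing bond block is rejected", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("mol", "  x", "", "  2  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0",
               "    1.5000    0.0000    0.0000 C   0  0",
               "M  END", "$$$$"), f)
  expect_error(read_ligand(f), "bond block")
})

test_that("pose sets append the crystal pose only when asked", {
  ds <- planted_signal_dataset(n_complexes = 1, seed = 5, n_poses = 20)
  ps <- ds$pose_sets[[1]]
  with_xtal <- assemble_pose_set(ps$receptor, ps$reference,
                                 lapply(ps$poses, `[[`, "mol"), "c1",
                                 include_crystal = TRUE)
  expect_length(with_xtal$poses, 21)
  expect_equal(sum(vapply(with_xtal$poses, `[[`, logical(1), "is_crystal")), 1)
  expect_true(is.na(with_xtal$poses[[21]]$dock_rank))
  expect_equal(vapply(with_xtal$poses[1:20], `[[`, integer(1), "dock_rank"), 1:20)
  no_xtal <- assemble_pose_set(ps$receptor, ps$reference,
                               lapply(ps$poses, `[[`, "mol"), "c1")
  expect_length(no_xtal$poses, 20)
})

test_that("cross-native poses are excluded in crossdock mode", {
  ds <- planted_signal_dataset(n_complexes = 1, seed = 5, n_poses = 4)
  ps <- ds$pose_sets[[1]]
  mols <- lapply(ps$poses, `[[`, "mol")
  expect_message(
    xd <- assemble_pose_set(ps$receptor, ps$reference, mols, "c1",
                            mode = "crossdock",
                            cross_native = c(TRUE, FALSE, FALSE, FALSE)),
    "cross-native")
  expect_length(xd$poses, 3)
  expect_equal(vapply(xd$poses, `[[`, integer(1), "dock_rank"), 2:4)
  # redock mode leaves them alone
  rd <- assemble_pose_set(ps$receptor, ps$reference, mols, "c1",
                          cross_native = c(TRUE, FALSE, FALSE, FALSE))
  expect_length(rd$poses, 4)
})

test_that("pose-set assembly rejects bad inputs", {
  ds <- planted_signal_dataset(n_complexes = 1, seed = 5, n_poses = 3)
  ps <- ds$pose_sets[[1]]
  mols <- lapply(ps$poses, `[[`, "mol")
  expect_error(assemble_pose_set(ps$receptor, ps$reference, list(), "c1"),
               "no docked poses")
  wrong <- point_ligand("I")  # formula cannot match any library ligand
  expect_error(assemble_pose_set(ps$receptor, ps$reference,
                                 c(mols[1:2], list(wrong)), "c1"),
               "pose 3")
  expect_warning(assemble_pose_set(ps$receptor, ps$reference, mols, "c1",
                                   max_poses = 2L),
                 "first 2")
})

test_that("metadata loading reproduces generated pose sets in file order", {
  dir <- withr::local_tempdir()
  md_path <- simulate_dataset(dir, n_complexes = 2, seed = 9, n_poses = 5)
  sets <- load_pose_sets(md_path)
  expect_length(sets, 2)
  expect_equal(vapply(sets[[1]]$poses, `[[`, integer(1), "dock_rank"), 1:5)
  # order-stability: record order in the pose file equals pose order
  ref <- planted_signal_dataset(n_complexes = 2, seed = 9, n_poses = 5)
  for (k in 1:5) {
    expect_equal(mol_coords(sets[[1]]$poses[[k]]$mol),
                 mol_coords(ref$pose_sets[[1]]$poses[[k]]$mol),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})
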