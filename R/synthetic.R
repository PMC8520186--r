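# coordinate helpers for the built-in ligand library
.ring_xyz <- function(n, r) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th), 0)
}
.chain_xyz <- function(n, step = 1.25, wobble = 0.44) {
  cbind(step * (seq_len(n) - 1), wobble * (seq_len(n) %% 2), 0)
}
.mk <- function(el, xyz, bonds, name, charge = NULL) {
  atoms <- data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  if (!is.null(charge)) atoms$charge <- charge
  b <- if (is.null(bonds)) NULL else
    data.frame(i = bonds[, 1], j = bonds[, 2], order = bonds[, 3],
               aromatic = bonds[, 3] == 4)
  ligand_mol(atoms, b, name = name)
}
.ring_bonds <- function(n, type = 4) {
  cbind(seq_len(n), c(seq_len(n)[-1], 1L), type)
}
# benzene ring with substituents attached radially at given vertices
.subst_ring <- function(sub_el, name, ring_n = 6L, r = 1.39, bond_len = 1.45,
                        sub_at = 1L, sub_order = 1) {
  xyz <- .ring_xyz(ring_n, r)
  sub_xyz <- xyz[sub_at, , drop = FALSE] * (r + bond_len) / r
  el <- c(rep("C", ring_n), sub_el)
  bonds <- rbind(.ring_bonds(ring_n),
                 cbind(sub_at, ring_n + seq_along(sub_el), sub_order))
  .mk(el, rbind(xyz, sub_xyz), bonds, name)
}

#' Built-in ligand library
#'
#' Twenty hand-coded small molecules with idealized 3D coordinates spanning
#' the nine-element ligand alphabet (C, N, O, S, P, F, Cl, Br, I) and the
#' featurizer branches: alkanes, an aliphatic ring, aromatics and
#' heteroaromatics, halides, alcohol, amide, nitrile, carboxylate (charged),
#' thioether and a phosphate ester.
#'
#' @return named list of `ligand_mol`.
#' @export
ligand_library <- function() {
  out <- list(
    ethane = .mk(c("C", "C"), .chain_xyz(2, 1.54, 0), cbind(1, 2, 1), "ethane"),
    butane = .mk(rep("C", 4), .chain_xyz(4),
                 cbind(1:3, 2:4, 1), "butane"),
    isobutane = .mk(rep("C", 4),
                    rbind(c(0, 0, 0), c(1.45, 0.45, 0), c(-1.45, 0.45, 0),
                          c(0, -0.9, 1.1)),
                    cbind(1, 2:4, 1), "isobutane"),
    cyclohexane = .mk(rep("C", 6), .ring_xyz(6, 1.5), .ring_bonds(6, 1),
                      "cyclohexane"),
    benzene = .mk(rep("C", 6), .ring_xyz(6, 1.39), .ring_bonds(6), "benzene"),
    toluene = .subst_ring("C", "toluene"),
    phenol = .subst_ring("O", "phenol"),
    fluorobenzene = .subst_ring("F", "fluorobenzene", bond_len = 1.35),
    chlorobenzene = .subst_ring("Cl", "chlorobenzene", bond_len = 1.74),
    bromobenzene = .subst_ring("Br", "bromobenzene", bond_len = 1.9),
    iodomethane = .mk(c("C", "I"), rbind(c(0, 0, 0), c(2.13, 0, 0)),
                      cbind(1, 2, 1), "iodomethane"),
    pyridine = .mk(c("N", rep("C", 5)), .ring_xyz(6, 1.38), .ring_bonds(6),
                   "pyridine"),
    furan = .mk(c("O", rep("C", 4)), .ring_xyz(5, 1.25), .ring_bonds(5),
                "furan"),
    thiophene = .mk(c("S", rep("C", 4)), .ring_xyz(5, 1.3), .ring_bonds(5),
                    "thiophene"),
    ethanol = .mk(c("C", "C", "O"), .chain_xyz(3, 1.45),
                  cbind(1:2, 2:3, 1), "ethanol"),
    acetamide = .mk(c("C", "C", "O", "N"),
                    rbind(c(-1.5, 0, 0), c(0, 0, 0), c(0.6, 1.05, 0),
                          c(0.7, -1.15, 0)),
                    cbind(2, c(1, 3, 4), c(1, 2, 1)), "acetamide"),
    acetate = .mk(c("C", "C", "O", "O"),
                  rbind(c(-1.5, 0, 0), c(0, 0, 0), c(0.6, 1.05, 0),
                        c(0.6, -1.1, 0)),
                  cbind(2, c(1, 3, 4), c(1, 2, 1)), "acetate",
                  charge = c(0L, 0L, 0L, -1L)),
    dimethyl_sulfide = .mk(c("C", "S", "C"), .chain_xyz(3, 1.8),
                           cbind(1:2, 2:3, 1), "dimethyl_sulfide"),
    methyl_phosphate = .mk(c("C", "O", "P", "O", "O", "O"),
                           rbind(c(-2.9, 0, 0), c(-1.55, 0.3, 0), c(0, 0, 0),
                                 c(0.5, 1.45, 0), c(0.6, -0.8, 1.15),
                                 c(0.6, -0.9, -1.1)),
                           cbind(c(1, 2, 3, 3, 3), c(2, 3, 4, 5, 6),
                                 c(1, 1, 2, 1, 1)), "methyl_phosphate"),
    acetonitrile = .mk(c("C", "C", "N"),
                       rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.62, 0, 0)),
                       cbind(1:2, 2:3, c(1, 3)), "acetonitrile"))
  out
}

# uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# rotation by a given angle about a random axis (Rodrigues)
rotation_by_angle <- function(theta) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a synthetic binding-pocket receptor
#'
#' Samples whole residues from the amino-acid templates and places them on a
#' bowl-shaped shell (radius 7-10 Angstrom, directions biased below the
#' equator) around the origin, where the reference ligand will sit. Residue
#' atoms are grown from the template bond graph with ~1.5 Angstrom steps and
#' clamped near their anchor, giving 30-80 heavy atoms with valid residue and
#' atom names so every atom receives an ECIF protein type.
#'
#' @param seed RNG seed; the structure is a deterministic function of it.
#' @param min_atoms,max_atoms heavy-atom bounds.
#' @return `protein_structure`.
#' @export
make_pocket <- function(seed, min_atoms = 30L, max_atoms = 80L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tpls <- amino_acid_templates()
  tpls <- tpls[!grepl("_", names(tpls))]
  rows <- list()
  n_placed <- 0L
  resno <- 0L
  while (n_placed < min_atoms) {
    tpl <- tpls[[sample(length(tpls), 1)]]
    na <- nrow(tpl$atoms)
    if (n_placed + na > max_atoms && n_placed >= min_atoms) break
    if (n_placed + na > max_atoms) next
    resno <- resno + 1L
    # anchor on the bowl shell
    z <- stats::runif(1, -1, 0.2)
    phi <- stats::runif(1, 0, 2 * pi)
    dir <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    anchor <- dir * stats::runif(1, 5, 8.5)
    # grow the residue from its bond graph
    local <- matrix(NA_real_, na, 3)
    local[1, ] <- c(0, 0, 0)
    placed <- 1L
    repeat {
      prog <- FALSE
      for (k in seq_len(nrow(tpl$bonds))) {
        ia <- match(tpl$bonds$a[k], tpl$atoms$name)
        ib <- match(tpl$bonds$b[k], tpl$atoms$name)
        for (pair in list(c(ia, ib), c(ib, ia))) {
          if (!is.na(local[pair[1], 1]) && is.na(local[pair[2], 1])) {
            for (try in 1:50) {
              step <- stats::rnorm(3)
              cand <- local[pair[1], ] + 1.5 * step / sqrt(sum(step^2))
              d <- sqrt(rowSums((local[!is.na(local[, 1]), , drop = FALSE] -
                                   matrix(cand, sum(!is.na(local[, 1])), 3,
                                          byrow = TRUE))^2))
              if (all(d > 1.0)) break
            }
            local[pair[2], ] <- cand
            placed <- placed + 1L
            prog <- TRUE
          }
        }
      }
      if (placed == na || !prog) break
    }
    # clamp atoms near the anchor, then keep the ligand site (origin) clear
    ex <- sqrt(rowSums(local^2))
    far <- ex > 2.5
    local[far, ] <- local[far, , drop = FALSE] * 2.5 / ex[far]
    xyz <- sweep(local, 2, anchor, `+`)
    rad <- sqrt(rowSums(xyz^2))
    close_in <- rad < 3.2
    xyz[close_in, ] <- xyz[close_in, , drop = FALSE] * 3.2 / rad[close_in]
    rows[[resno]] <- data.frame(element = tpl$atoms$element, x = xyz[, 1],
                                y = xyz[, 2], z = xyz[, 3],
                                resname = tpl$resname, resno = resno,
                                chain = "A", atom_name = tpl$atoms$name,
                                stringsAsFactors = FALSE)
    n_placed <- n_placed + na
  }
  protein_structure(do.call(rbind, rows))
}

#' Generate a docked-pose ensemble with a controlled RMSD spectrum
#'
#' Poses are rigid-body perturbations of the reference (random rotation about
#' the centroid plus translation) with a small constant per-atom jitter
#' (0.05 Angstrom) for realism. A requested fraction of poses is near-native:
#' perturbation magnitudes are rescaled until the realized symmetry-corrected
#' RMSD falls on the intended side of the cutoff, so the class balance is
#' controlled. Negative-pose translations are biased upward, out of the
#' pocket bowl, so near-native poses genuinely make more receptor contacts.
#' Docking ranks are assigned from a noisy function of RMSD (rank is
#' informative but imperfect, as in real docking output).
#'
#' @param reference `ligand_mol` centered in the pocket frame.
#' @param n_poses number of docked poses (<= 20 by convention).
#' @param positive_fraction requested fraction of near-native poses.
#' @param cutoff near-native cutoff in Angstrom.
#' @param seed RNG seed.
#' @param rank_noise_sd sd of the Gaussian noise added to RMSD before
#'   ranking.
#' @param jitter per-atom Gaussian jitter sd in Angstrom.
#' @param scale global multiplier on all perturbation magnitudes; 0 gives
#'   poses identical to the reference (RMSD 0).
#' @return list of `ligand_mol` in dock-rank order.
#' @export
make_pose_ensemble <- function(reference, n_poses = 20L,
                               positive_fraction = 0.5, cutoff = 2.0,
                               seed = 1L, rank_noise_sd = 1.5,
                               jitter = 0.05, scale = 1) {
  stopifnot(n_poses >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_pos <- round(n_poses * positive_fraction)
  want_pos <- c(rep(TRUE, n_pos), rep(FALSE, n_poses - n_pos))
  jitter <- jitter * scale
  ctr <- colMeans(mol_coords(reference))
  perturb <- function(trans_mag, angle, up_bias) {
    dir <- stats::rnorm(3)
    if (up_bias) dir[3] <- abs(dir[3]) + 0.5
    dir <- dir / sqrt(sum(dir^2))
    R <- rotation_by_angle(angle)
    m <- reference
    xyz <- mol_coords(reference)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + dir * trans_mag, `+`)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter), nrow(xyz))
    m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
    m
  }
  mols <- vector("list", n_poses)
  rmsds <- numeric(n_poses)
  for (q in seq_len(n_poses)) {
    if (want_pos[q]) {
      mag <- scale * stats::runif(1, 0.05, 1.4)
      ang <- scale * stats::runif(1, 0, 0.5)
    } else {
      mag <- scale * stats::runif(1, 2.6, 7.5)
      ang <- scale * stats::runif(1, 0, pi)
    }
    m <- perturb(mag, ang, up_bias = !want_pos[q])
    r <- symmetry_rmsd(m, reference)
    tries <- 0L
    while (scale > 0 &&
           ((want_pos[q] && r >= cutoff * 0.95) ||
            (!want_pos[q] && r <= cutoff * 1.15)) && tries < 12L) {
      f <- if (want_pos[q]) 0.7 else 1.35
      mag <- mag * f; ang <- ang * f
      m <- perturb(mag, min(ang, pi), up_bias = !want_pos[q])
      r <- symmetry_rmsd(m, reference)
      tries <- tries + 1L
    }
    mols[[q]] <- m
    rmsds[q] <- r
  }
  noisy <- rmsds + stats::rnorm(n_poses, 0, rank_noise_sd)
  mols[order(noisy)]
}

#' Generate one synthetic complex as a pose set
#'
#' A pocket, a library ligand randomly rotated at the pocket centre as the
#' crystal reference, and a docked ensemble around it.
#'
#' @param complex_id identifier.
#' @param seed RNG seed (pocket, reference orientation and ensemble derive
#'   from it).
#' @param ligand `ligand_mol`; default samples from [ligand_library()].
#' @param n_poses,positive_fraction,include_crystal see
#'   [make_pose_ensemble()] / [assemble_pose_set()].
#' @return `pose_set`.
#' @export
make_complex <- function(complex_id, seed, ligand = NULL, n_poses = 20L,
                         positive_fraction = 0.5, include_crystal = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(ligand)) {
    lib <- ligand_library()
    ligand <- lib[[sample(length(lib), 1)]]
  }
  reference <- transform_mol(
    transform_mol(ligand, diag(3), -colMeans(mol_coords(ligand))),
    random_rotation())
  pocket <- make_pocket(seed + 104729L)
  poses <- make_pose_ensemble(reference, n_poses = n_poses,
                              positive_fraction = positive_fraction,
                              seed = seed + 15485863L)
  assemble_pose_set(pocket, reference, poses, complex_id = complex_id,
                    receptor_id = paste0(complex_id, "_rec"),
                    program = "synthetic", mode = "redock",
                    include_crystal = include_crystal)
}

#' Generate a planted-signal dataset of synthetic complexes
#'
#' Labels equal (RMSD < cutoff) by construction, and near-native poses sit
#' closer to the pocket than decoys, so interaction features (ELEM, ECIF,
#' Vina terms) carry signal while ligand-only features do not: the dataset
#' is the parameter-recovery harness for the model stage and mirrors the
#' ligand-only control logic.
#'
#' @param n_complexes number of complexes.
#' @param seed master seed; per-complex seeds derive from it.
#' @param n_poses,positive_fraction,include_crystal per-complex settings.
#' @return list with `pose_sets` (list of `pose_set`) and `truth`
#'   (data.frame of per-pose RMSD and label).
#' @export
planted_signal_dataset <- function(n_complexes = 200L, seed = 1L,
                                   n_poses = 20L, positive_fraction = 0.5,
                                   include_crystal = FALSE) {
  lib <- ligand_library()
  pose_sets <- lapply(seq_len(n_complexes), function(i) {
    make_complex(sprintf("cx%04d", i), seed = seed + 7919L * i,
                 ligand = lib[[((i - 1) %% length(lib)) + 1]],
                 n_poses = n_poses, positive_fraction = positive_fraction,
                 include_crystal = include_crystal)
  })
  truth <- do.call(rbind, lapply(pose_sets, label_pose_set))
  list(pose_sets = pose_sets, truth = truth)
}

#' Write a synthetic dataset to disk in the structio input formats
#'
#' Emits one receptor PDB, one crystal-reference SDF and one multi-record
#' pose SDF per complex, plus the metadata CSV contract consumed by
#' [load_pose_sets()].
#'
#' @param dir output directory (created if needed).
#' @param n_complexes,seed,n_poses,positive_fraction generator settings.
#' @return path of the metadata CSV.
#' @export
simulate_dataset <- function(dir, n_complexes = 10L, seed = 1L, n_poses = 20L,
                             positive_fraction = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- planted_signal_dataset(n_complexes, seed = seed, n_poses = n_poses,
                               positive_fraction = positive_fraction)
  md <- lapply(ds$pose_sets, function(ps) {
    id <- ps$complex_id
    rec <- file.path(dir, paste0(id, "_receptor.pdb"))
    ref <- file.path(dir, paste0(id, "_reference.sdf"))
    lig <- file.path(dir, paste0(id, "_poses.sdf"))
    write_pocket_pdb(ps$receptor, rec)
    write_sdf(ps$reference, ref)
    write_sdf(lapply(ps$poses, `[[`, "mol"), lig)
    data.frame(complex_id = id, receptor_id = ps$receptor_id,
               ligand_file = basename(lig), reference_file = basename(ref),
               receptor_file = basename(rec), program = "synthetic",
               mode = ps$mode, stringsAsFactors = FALSE)
  })
  path <- file.path(dir, "metadata.csv")
  utils::write.csv(do.call(rbind, md), path, row.names = FALSE)
  path
}

#' Write a protein_structure as a PDB file
#' @param prot `protein_structure`.
#' @param path output PDB path.
#' @export
write_pocket_pdb <- function(prot, path) {
  a <- prot$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resname, eleno = seq_len(nrow(a)),
                   elety = a$atom_name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}
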