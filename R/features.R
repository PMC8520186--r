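.elem_protein_alphabet <- c("C", "N", "O", "S")
.elem_ligand_alphabet <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

# squared cross-distance matrix between two xyz matrices
cross_dist2 <- function(P, L) {
  outer(rowSums(P^2), rep(1, nrow(L))) +
    outer(rep(1, nrow(P)), rowSums(L^2)) - 2 * (P %*% t(L))
}

feature_name_safe <- function(x) gsub(";", ".", x, fixed = TRUE)

#' ELEM featurization: element-pair contact counts
#'
#' Counts protein-ligand heavy-atom pairs within the distance cutoff for
#' each combination of the four protein elements (C, N, O, S) and nine
#' ligand elements (C, N, O, S, P, F, Cl, Br, I): 36 features. Distance
#' comparison is inclusive. Atoms with elements outside the alphabets are
#' ignored.
#'
#' @param receptor `protein_structure`.
#' @param pose_mol `ligand_mol`.
#' @param cutoff contact cutoff in Angstrom (default 6.0).
#' @return named numeric vector of length 36.
#' @export
elem_featurize <- function(receptor, pose_mol, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  pe <- receptor$atoms$element
  le <- pose_mol$atoms$element
  keep_p <- pe %in% .elem_protein_alphabet
  keep_l <- le %in% .elem_ligand_alphabet
  counts <- matrix(0L, length(.elem_protein_alphabet),
                   length(.elem_ligand_alphabet),
                   dimnames = list(.elem_protein_alphabet, .elem_ligand_alphabet))
  if (any(keep_p) && any(keep_l)) {
    d2 <- cross_dist2(protein_coords(receptor)[keep_p, , drop = FALSE],
                      mol_coords(pose_mol)[keep_l, , drop = FALSE])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      tab <- table(factor(pe[keep_p][hit[, 1]], levels = .elem_protein_alphabet),
                   factor(le[keep_l][hit[, 2]], levels = .elem_ligand_alphabet))
      counts <- counts + unclass(tab)
    }
  }
  v <- as.vector(t(counts))
  names(v) <- paste0("ELEM__",
                     rep(.elem_protein_alphabet, each = length(.elem_ligand_alphabet)),
                     "__", rep(.elem_ligand_alphabet, length(.elem_protein_alphabet)))
  v
}

#' ECIF connectivity type of a ligand atom
#'
#' Key `Element;Valence;HeavyNeighbors;AttachedH;IsAromatic;IsInRing`.
#' Heavy-neighbour counts and ring/aromatic flags come from the bond graph;
#' attached hydrogens from implicit-valence completion (aromatic bonds
#' contribute 1.5 to the bond-order sum, rounded half-to-even); the valence
#' is the rounded bond-order sum plus attached hydrogens. Atoms with
#' elements outside the ligand alphabet get `NA` (excluded from counts).
#'
#' @param mol `ligand_mol`.
#' @param index atom index; `NULL` types every atom.
#' @return character key(s).
#' @export
ecif_atom_type <- function(mol, index = NULL) {
  stopifnot(inherits(mol, "ligand_mol"))
  bos <- round(mol_bond_order_sum(mol))
  nH <- mol_implicit_h(mol)
  deg <- mol_degree(mol)
  keys <- ecif_key(mol$atoms$element, bos + nH, deg, nH,
                   mol$atoms$aromatic, mol$atoms$in_ring)
  keys[!(mol$atoms$element %in% .elem_ligand_alphabet)] <- NA_character_
  if (is.null(index)) keys else keys[index]
}

#' ECIF types of receptor atoms by residue/atom-name lookup
#'
#' Protein atoms are typed from the amino-acid templates via
#' [protein_atom_annotations()]; atoms of nonstandard residues or with
#' unknown names get `NA` and are excluded from pair counts (their tally is
#' returned as an attribute).
#'
#' @param receptor `protein_structure`.
#' @return character vector of type keys with attribute `n_untyped`.
#' @export
ecif_receptor_types <- function(receptor) {
  ann <- protein_atom_annotations()
  key <- paste(receptor$atoms$resname, receptor$atoms$atom_name)
  hit <- match(key, paste(ann$resname, ann$atom_name))
  types <- ann$ecif_type[hit]
  attr(types, "n_untyped") <- sum(is.na(types))
  types
}

.posepower_cache <- new.env(parent = emptyenv())

cached <- function(key, value_fn) {
  if (is.null(.posepower_cache[[key]]))
    assign(key, value_fn(), envir = .posepower_cache)
  .posepower_cache[[key]]
}

#' Load the ECIF protein atom-type vocabulary (22 types)
#' @return character vector.
#' @export
ecif_protein_vocabulary <- function() {
  cached("vocab_protein", function() {
    path <- system.file("extdata", "ecif_protein_types.txt", package = "posepower")
    if (!nzchar(path)) stop("ecif_protein_vocabulary: vocabulary file missing")
    readLines(path)
  })
}

#' Load the ECIF ligand atom-type vocabulary (71 types)
#'
#' The published ligand alphabet was derived from a large reference ligand
#' corpus; this package ships a synthetic reconstruction at the same width
#' (71 types over C, N, O, S, P, F, Cl, Br, I), see the package vignette.
#' @return character vector.
#' @export
ecif_ligand_vocabulary <- function() {
  cached("vocab_ligand", function() {
    path <- system.file("extdata", "ecif_ligand_types_synthetic.txt",
                        package = "posepower")
    if (!nzchar(path)) stop("ecif_ligand_vocabulary: vocabulary file missing")
    readLines(path)
  })
}

ecif_feature_names <- function() {
  cached("ecif_names", function() {
    vp <- ecif_protein_vocabulary(); vl <- ecif_ligand_vocabulary()
    paste0("ECIF__", feature_name_safe(rep(vp, each = length(vl))),
           "__", feature_name_safe(rep(vl, length(vp))))
  })
}

#' ECIF featurization: connectivity-typed contact counts
#'
#' Counts protein-ligand heavy-atom pairs within the cutoff for every
#' combination of the 22 protein and 71 ligand connectivity types
#' (22 x 71 = 1562 features). Pairs involving an untyped atom are ignored.
#'
#' @param receptor `protein_structure`.
#' @param pose_mol `ligand_mol`.
#' @param cutoff contact cutoff in Angstrom (default 6.0, inclusive).
#' @param receptor_types optional precomputed [ecif_receptor_types()] result.
#' @return named numeric vector of length 1562.
#' @export
ecif_featurize <- function(receptor, pose_mol, cutoff = 6.0,
                           receptor_types = NULL) {
  stopifnot(cutoff > 0)
  vp <- ecif_protein_vocabulary()
  vl <- ecif_ligand_vocabulary()
  if (is.null(receptor_types)) receptor_types <- ecif_receptor_types(receptor)
  lig_types <- ecif_atom_type(pose_mol)
  keep_p <- !is.na(receptor_types) & receptor_types %in% vp
  keep_l <- !is.na(lig_types) & lig_types %in% vl
  counts <- matrix(0L, length(vp), length(vl), dimnames = list(vp, vl))
  if (any(keep_p) && any(keep_l)) {
    d2 <- cross_dist2(protein_coords(receptor)[keep_p, , drop = FALSE],
                      mol_coords(pose_mol)[keep_l, , drop = FALSE])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      tab <- table(factor(receptor_types[keep_p][hit[, 1]], levels = vp),
                   factor(lig_types[keep_l][hit[, 2]], levels = vl))
      counts <- counts + unclass(tab)
    }
  }
  v <- as.vector(t(counts))
  names(v) <- ecif_feature_names()
  v
}

# van der Waals radii used by the Vina-style terms (Angstrom)
.vdw_radii <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
                F = 1.5, Cl = 1.8, Br = 2.0, I = 2.2)
.vdw_default <- 1.8

vdw_radius <- function(el) {
  r <- .vdw_radii[el]
  if (any(is.na(r))) {
    warning("vina_terms: unknown element(s) ",
            paste(unique(el[is.na(r)]), collapse = ","),
            "; using generic vdW radius ", .vdw_default)
    r[is.na(r)] <- .vdw_default
  }
  unname(r)
}

# ligand-side Vina interaction classes from the heavy-atom graph
ligand_vina_classes <- function(mol) {
  nb <- mol_neighbors(mol)
  el <- mol$atoms$element
  nH <- mol_implicit_h(mol)
  hydroph <- el == "C" & !vapply(seq_along(nb), function(i)
    any(el[nb[[i]]] %in% c("N", "O", "S")), logical(1))
  donor <- el %in% c("N", "O") & nH > 0
  acceptor <- el %in% c("N", "O")
  list(hydrophobic = hydroph, donor = donor, acceptor = acceptor)
}

#' Vina-style empirical energy terms
#'
#' The five steric/interaction terms of the AutoDock Vina functional form,
#' summed over protein-ligand heavy-atom pairs with interatomic distance
#' r <= 8 Angstrom, as functions of the surface distance
#' d = r - (R_i + R_j): gauss1 = exp(-(d/0.5)^2); gauss2 = exp(-((d-3)/2)^2);
#' repulsion = d^2 for d < 0; hydrophobic = linear ramp 1 to 0 over
#' d in [0.5, 1.5], restricted to hydrophobic-carbon pairs; hbond = linear
#' ramp 1 to 0 over d in [-0.7, 0], restricted to donor-acceptor pairs.
#' Hydrophobic carbons are carbons with no bonded N/O/S; donors are N/O
#' bearing a hydrogen, acceptors any N/O (receptor classes come from the
#' residue templates, ligand classes from the bond graph).
#'
#' @param receptor `protein_structure`.
#' @param pose_mol `ligand_mol`.
#' @param cutoff pair cutoff on r in Angstrom (default 8.0).
#' @return named numeric vector: gauss1, gauss2, repulsion, hydrophobic, hbond.
#' @export
vina_terms <- function(receptor, pose_mol, cutoff = 8.0) {
  ann <- protein_atom_annotations()
  hit <- match(paste(receptor$atoms$resname, receptor$atoms$atom_name),
               paste(ann$resname, ann$atom_name))
  p_h <- ann$hydrophobic[hit]; p_h[is.na(p_h)] <- FALSE
  p_d <- ann$donor[hit]; p_d[is.na(p_d)] <- FALSE
  p_a <- ann$acceptor[hit]; p_a[is.na(p_a)] <- FALSE
  lc <- ligand_vina_classes(pose_mol)
  r <- sqrt(pmax(cross_dist2(protein_coords(receptor), mol_coords(pose_mol)), 0))
  Rsum <- outer(vdw_radius(receptor$atoms$element),
                vdw_radius(pose_mol$atoms$element), `+`)
  within <- r <= cutoff
  d <- r - Rsum
  gauss1 <- sum(exp(-(d[within] / 0.5)^2))
  gauss2 <- sum(exp(-((d[within] - 3) / 2)^2))
  repulsion <- sum((d[within & d < 0])^2)
  ramp <- function(x, lo, hi) pmin(1, pmax(0, (hi - x) / (hi - lo)))
  hmask <- within & outer(p_h, lc$hydrophobic, `&`)
  hydrophobic <- sum(ramp(d[hmask], 0.5, 1.5))
  damask <- within & (outer(p_d, lc$acceptor, `&`) | outer(p_a, lc$donor, `&`))
  hbond <- sum(ramp(d[damask], -0.7, 0))
  c(VINA__gauss1 = gauss1, VINA__gauss2 = gauss2, VINA__repulsion = repulsion,
    VINA__hydrophobic = hydrophobic, VINA__hbond = hbond)
}

#' Docking-rank feature of a pose
#'
#' The 1-based rank emitted by the docking program. Crystal poses and pooled
#' multi-program sets have no rank: the feature is missing (NA) and only
#' models trained without the rank family accept such rows.
#'
#' @param pose a pose entry of a `pose_set` (list with `dock_rank`).
#' @return named numeric vector of length 1.
#' @export
rank_feature <- function(pose) {
  r <- pose$dock_rank
  c(RANK__dock_rank = if (is.null(r) || is.na(r)) NA_real_ else as.numeric(r))
}

#' Ligand-only control featurization
#'
#' A receptor-independent 3D descriptor of the ligand conformation: element
#' counts over the nine-element ligand alphabet, a histogram of heavy-atom
#' pairwise distances (1 Angstrom bins over [0, 10), overflow in the last
#' bin) and the radius of gyration. Serves as a control: a model trained on
#' these features can only exploit ligand-internal geometry, never
#' protein-ligand interactions.
#'
#' @param pose_mol `ligand_mol`.
#' @return named numeric vector of length 20.
#' @export
ligand_control_featurize <- function(pose_mol) {
  el_counts <- table(factor(pose_mol$atoms$element, levels = .elem_ligand_alphabet))
  xyz <- mol_coords(pose_mol)
  n <- nrow(xyz)
  breaks <- c(seq(0, 9, by = 1), Inf)
  if (n >= 2) {
    dd <- stats::dist(xyz)
    h <- as.vector(table(cut(as.vector(dd), breaks, right = FALSE)))
    rg <- sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  } else {
    h <- rep(0, 10)
    rg <- 0
  }
  v <- c(as.numeric(el_counts), h, rg)
  names(v) <- c(paste0("LCTL__count_", .elem_ligand_alphabet),
                paste0("LCTL__dhist_", seq_len(10)), "LCTL__rgyr")
  v
}

.feature_families <- c("elem", "ecif", "vina", "rank", "ligand_control")

#' Feature schema for a family selection
#' @param families subset of elem, ecif, vina, rank, ligand_control.
#' @return list with `names` and `family` tags.
#' @export
feature_schema <- function(families) {
  families <- match.arg(families, .feature_families, several.ok = TRUE)
  blocks <- list(
    elem = paste0("ELEM__",
                  rep(.elem_protein_alphabet, each = length(.elem_ligand_alphabet)),
                  "__", rep(.elem_ligand_alphabet, length(.elem_protein_alphabet))),
    ecif = ecif_feature_names(),
    vina = paste0("VINA__", c("gauss1", "gauss2", "repulsion", "hydrophobic", "hbond")),
    rank = "RANK__dock_rank",
    ligand_control = c(paste0("LCTL__count_", .elem_ligand_alphabet),
                       paste0("LCTL__dhist_", seq_len(10)), "LCTL__rgyr"))
  nm <- unlist(blocks[families], use.names = FALSE)
  list(names = nm,
       family = rep(families, vapply(blocks[families], length, integer(1))),
       version = "posepower-1")
}

#' Assemble the per-pose feature table of one or more pose sets
#'
#' Computes the requested feature families for every pose and returns one
#' row per pose with identifiers, symmetry-corrected RMSD and near-native
#' label followed by the feature columns (a fixed schema across all sets).
#'
#' @param pose_sets a `pose_set` or list of them.
#' @param families feature families to concatenate.
#' @param cutoff contact cutoff for elem/ecif in Angstrom.
#' @param rmsd_cutoff near-native label cutoff in Angstrom.
#' @return data.frame (DatasetTable): complex_id, pose_id, dock_rank,
#'   is_crystal, rmsd, label, then features.
#' @export
assemble_features <- function(pose_sets, families = c("ecif", "vina"),
                              cutoff = 6.0, rmsd_cutoff = 2.0) {
  if (inherits(pose_sets, "pose_set")) pose_sets <- list(pose_sets)
  if (length(families) == 0) stop("assemble_features: empty family set")
  families <- match.arg(families, .feature_families, several.ok = TRUE)
  schema <- feature_schema(families)
  if ("rank" %in% families) {
    has_rank <- vapply(pose_sets, function(ps)
      any(!vapply(ps$poses, function(p) is.null(p$dock_rank) || is.na(p$dock_rank),
                  logical(1))), logical(1))
    if (!all(has_rank))
      stop("assemble_features: rank family requested but pose set(s) ",
           paste(vapply(pose_sets[!has_rank], `[[`, character(1), "complex_id"),
                 collapse = ", "),
           " carry no docking ranks; train a rank-free model instead")
  }
  rows <- lapply(pose_sets, function(ps) {
    lab <- label_pose_set(ps, cutoff = rmsd_cutoff)
    rtypes <- if ("ecif" %in% families) ecif_receptor_types(ps$receptor) else NULL
    feats <- t(vapply(seq_along(ps$poses), function(k) {
      p <- ps$poses[[k]]
      unlist(lapply(families, function(f) switch(f,
        elem = elem_featurize(ps$receptor, p$mol, cutoff),
        ecif = ecif_featurize(ps$receptor, p$mol, cutoff, receptor_types = rtypes),
        vina = vina_terms(ps$receptor, p$mol),
        rank = rank_feature(p),
        ligand_control = ligand_control_featurize(p$mol))))
    }, numeric(length(schema$names))))
    colnames(feats) <- schema$names
    cbind(lab, as.data.frame(feats, check.names = FALSE))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "schema") <- schema
  out
}

#' Feature columns of a dataset table
#' @param table data.frame from [assemble_features()].
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("complex_id", "pose_id", "dock_rank", "is_crystal",
                          "rmsd", "label", "score"))
}

#' Write a dataset table to CSV or Parquet (by extension)
#' @param table data.frame.
#' @param path output path (.csv or .parquet).
#' @export
write_dataset <- function(table, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("write_dataset: the arrow package is required for Parquet output")
    arrow::write_parquet(table, path)
  } else {
    utils::write.csv(table, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset table written by [write_dataset()]
#' @param path .csv or .parquet file.
#' @return data.frame.
#' @export
read_dataset <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("read_dataset: the arrow package is required for Parquet input")
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
}
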