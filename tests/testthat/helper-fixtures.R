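# shared fixtures and independent oracles for the test suite

# a toy receptor from an explicit atom table
toy_receptor <- function(atoms) {
  defaults <- data.frame(resname = "ALA", resno = 1L, chain = "A",
                         atom_name = "CB", stringsAsFactors = FALSE)
  for (col in names(defaults))
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  protein_structure(atoms)
}

# single-atom ligand at a position
point_ligand <- function(element = "C", x = 0, y = 0, z = 0) {
  ligand_mol(data.frame(element = element, x = x, y = y, z = z), NULL)
}

# random synthetic complex pair (receptor atom cloud + ligand) for oracles;
# receptor atoms carry valid residue/atom names so ECIF typing works
random_complex <- function(seed, n_rec = 50, lig = NULL) {
  set.seed(seed)
  ann <- posepower::protein_atom_annotations()
  pick <- ann[sample(nrow(ann), n_rec, replace = TRUE), ]
  rec <- protein_structure(data.frame(
    element = pick$element,
    x = runif(n_rec, -8, 8), y = runif(n_rec, -8, 8), z = runif(n_rec, -8, 8),
    resname = pick$resname, resno = seq_len(n_rec), chain = "A",
    atom_name = pick$atom_name, stringsAsFactors = FALSE))
  if (is.null(lig)) {
    lib <- ligand_library()
    lig <- lib[[sample(length(lib), 1)]]
  }
  lig <- transform_mol(lig, diag(3), runif(3, -3, 3))
  list(receptor = rec, ligand = lig)
}

# O(N*M) double-loop ELEM oracle
elem_oracle <- function(rec, lig, cutoff = 6.0) {
  pa <- c("C", "N", "O", "S")
  la <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  counts <- matrix(0, length(pa), length(la), dimnames = list(pa, la))
  for (i in seq_len(nrow(rec$atoms))) {
    for (j in seq_len(nrow(lig$atoms))) {
      pe <- rec$atoms$element[i]; le <- lig$atoms$element[j]
      if (!(pe %in% pa) || !(le %in% la)) next
      d <- sqrt((rec$atoms$x[i] - lig$atoms$x[j])^2 +
                  (rec$atoms$y[i] - lig$atoms$y[j])^2 +
                  (rec$atoms$z[i] - lig$atoms$z[j])^2)
      if (d <= cutoff) counts[pe, le] <- counts[pe, le] + 1
    }
  }
  as.vector(t(counts))
}

# O(N*M) double-loop typed ECIF oracle
ecif_oracle <- function(rec, lig, cutoff = 6.0) {
  vp <- ecif_protein_vocabulary(); vl <- ecif_ligand_vocabulary()
  pt <- ecif_receptor_types(rec)
  lt <- ecif_atom_type(lig)
  counts <- matrix(0, length(vp), length(vl), dimnames = list(vp, vl))
  for (i in seq_len(nrow(rec$atoms))) {
    for (j in seq_len(nrow(lig$atoms))) {
      if (is.na(pt[i]) || is.na(lt[j])) next
      if (!(pt[i] %in% vp) || !(lt[j] %in% vl)) next
      d <- sqrt((rec$atoms$x[i] - lig$atoms$x[j])^2 +
                  (rec$atoms$y[i] - lig$atoms$y[j])^2 +
                  (rec$atoms$z[i] - lig$atoms$z[j])^2)
      if (d <= cutoff) counts[pt[i], lt[j]] <- counts[pt[i], lt[j]] + 1
    }
  }
  as.vector(t(counts))
}

# direct per-pair Vina formula oracle
vina_oracle <- function(rec, lig, cutoff = 8.0) {
  radii <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
             F = 1.5, Cl = 1.8, Br = 2.0, I = 2.2)
  ann <- posepower::protein_atom_annotations()
  key <- paste(rec$atoms$resname, rec$atoms$atom_name)
  hit <- match(key, paste(ann$resname, ann$atom_name))
  lc <- posepower:::ligand_vina_classes(lig)
  out <- c(gauss1 = 0, gauss2 = 0, repulsion = 0, hydrophobic = 0, hbond = 0)
  for (i in seq_len(nrow(rec$atoms))) {
    for (j in seq_len(nrow(lig$atoms))) {
      r <- sqrt((rec$atoms$x[i] - lig$atoms$x[j])^2 +
                  (rec$atoms$y[i] - lig$atoms$y[j])^2 +
                  (rec$atoms$z[i] - lig$atoms$z[j])^2)
      if (r > cutoff) next
      d <- r - radii[rec$atoms$element[i]] - radii[lig$atoms$element[j]]
      out["gauss1"] <- out["gauss1"] + exp(-(d / 0.5)^2)
      out["gauss2"] <- out["gauss2"] + exp(-((d - 3) / 2)^2)
      if (d < 0) out["repulsion"] <- out["repulsion"] + d^2
      h <- !is.na(hit[i]) && ann$hydrophobic[hit[i]] && lc$hydrophobic[j]
      if (h) out["hydrophobic"] <- out["hydrophobic"] +
          min(1, max(0, (1.5 - d) / 1))
      da <- !is.na(hit[i]) && ((ann$donor[hit[i]] && lc$acceptor[j]) ||
                                 (ann$acceptor[hit[i]] && lc$donor[j]))
      if (da) out["hbond"] <- out["hbond"] + min(1, max(0, -d / 0.7))
    }
  }
  unname(out)
}

# exhaustive symmetry-RMSD oracle: all element- and adjacency-preserving
# permutations (for molecules with <= 8 heavy atoms)
exhaustive_rmsd <- function(pose, ref) {
  n <- nrow(ref$atoms)
  stopifnot(n <= 8)
  adj <- function(m) {
    A <- matrix(0L, n, n)
    for (k in seq_len(nrow(m$bonds))) {
      A[m$bonds$i[k], m$bonds$j[k]] <- 1L
      A[m$bonds$j[k], m$bonds$i[k]] <- 1L
    }
    A
  }
  Aref <- adj(ref); Apose <- adj(pose)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  Cref <- as.matrix(ref$atoms[, c("x", "y", "z")])
  Cpose <- as.matrix(pose$atoms[, c("x", "y", "z")])
  for (p in perms(seq_len(n))) {
    if (any(ref$atoms$element != pose$atoms$element[p])) next
    if (!all(Aref == Apose[p, p])) next
    v <- mean(rowSums((Cref - Cpose[p, , drop = FALSE])^2))
    best <- min(best, v)
  }
  sqrt(best)
}

# dynamic-programming LCS length oracle
lcs_length <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- matrix(0L, length(A) + 1, length(B) + 1)
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      m[i + 1, j + 1] <- if (A[i] == B[j]) m[i, j] + 1L
        else max(m[i, j + 1], m[i + 1, j])
    }
  }
  m[length(A) + 1, length(B) + 1]
}

# random scored-pose fixture for metric property tests
random_scored_sets <- function(seed, n_cx = 8, max_poses = 10) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_cx), function(i) {
    np <- sample(2:max_poses, 1)
    data.frame(complex_id = sprintf("c%02d", i),
               pose_id = sprintf("c%02d_p%d", i, seq_len(np)),
               dock_rank = seq_len(np), is_crystal = FALSE,
               rmsd = runif(np, 0, 8), stringsAsFactors = FALSE)
  }))
  scored_poses(rows, scores = runif(nrow(rows)), drop_crystal = FALSE)
}

# random similarity structure for clustered-split constraint checks; link
# density scales as ~1/n so components stay small relative to n
random_similarity_structure <- function(seed, n) {
  set.seed(seed)
  ids <- sprintf("c%03d", seq_len(n))
  sym <- function(deg) {
    p_hi <- deg / n
    m <- diag(1, n)
    hi <- matrix(runif(n * n) < p_hi, n)
    v <- matrix(runif(n * n, 0.3, 1), n)
    lo <- matrix(runif(n * n, 0, 0.45), n)
    m[upper.tri(m)] <- ifelse(hi, v, lo)[upper.tri(m)]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dimnames(m) <- list(ids, ids)
    m
  }
  structure(list(ids = ids, protein_sim = sym(0.5), ligand_sim = sym(2)),
            class = "similarity_matrix")
}

# small synthetic dataset shared by the model/eval tests (built once)
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- planted_signal_dataset(n_complexes = 24, seed = 420, n_poses = 12)
      ft <- assemble_features(ds$pose_sets, families = c("elem", "vina", "rank"))
      cache <<- list(ds = ds, ft = ft)
    }
    cache
  }
})
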