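#' Path-based topological fingerprint of a ligand
#'
#' Enumerates all simple bond paths of 1 to `max_path` bonds over the
#' heavy-atom graph, canonicalizes each path string (elements and bond
#' orders, reading direction chosen lexicographically) and hashes it onto a
#' fixed-length bit set, in the spirit of the RDKit topological (Daylight)
#' fingerprint. Used for ligand structural similarity in clustered splits.
#'
#' @param mol `ligand_mol`.
#' @param n_bits fingerprint length (default 2048).
#' @param max_path maximum path length in bonds (default 7).
#' @return sorted integer vector of on-bit positions (1-based).
#' @export
topological_fingerprint <- function(mol, n_bits = 2048L, max_path = 7L) {
  stopifnot(inherits(mol, "ligand_mol"))
  if (n_atoms(mol) == 0) stop("topological_fingerprint: empty molecule")
  nb <- mol_neighbors(mol)
  el <- mol$atoms$element
  # bond order lookup
  ord <- new.env()
  for (k in seq_len(nrow(mol$bonds))) {
    key <- paste(pmin(mol$bonds$i[k], mol$bonds$j[k]),
                 pmax(mol$bonds$i[k], mol$bonds$j[k]))
    assign(key, mol$bonds$order[k], envir = ord)
  }
  bond_ord <- function(i, j) get(paste(min(i, j), max(i, j)), envir = ord)
  paths <- character(0)
  # depth-first enumeration of simple paths from every atom
  walk <- function(path) {
    last <- path[length(path)]
    for (nxt in nb[[last]]) {
      if (nxt %in% path) next
      p2 <- c(path, nxt)
      os <- vapply(seq_len(length(p2) - 1L),
                   function(q) bond_ord(p2[q], p2[q + 1L]), numeric(1))
      fwd <- paste(el[p2], c(format(os), ""), sep = "", collapse = "|")
      rev_ <- paste(el[rev(p2)], c(format(rev(os)), ""), sep = "", collapse = "|")
      paths[[length(paths) + 1L]] <<- if (fwd <= rev_) fwd else rev_
      if (length(p2) <= max_path) walk(p2)
    }
  }
  for (a in seq_len(n_atoms(mol))) walk(a)
  if (length(paths) == 0) paths <- paste0("atom:", el)  # single atoms
  bits <- vapply(unique(paths), fnv1a_bit, integer(1), n_bits = n_bits,
                 USE.NAMES = FALSE)
  sort(unique(bits))
}

# FNV-1a string hash folded onto [1, n_bits]; double arithmetic kept exact
# below 2^53 by reducing modulo 2^32 after each multiply
fnv1a_bit <- function(s, n_bits) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% n_bits) + 1L
}

bitwXor_dbl <- function(a, b) {
  # a < 2^32, b < 2^8: xor via 16-bit halves to stay in integer range
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b))
  hi <- as.integer(a %/% 65536)
  hi * 65536 + lo
}

#' Tanimoto similarity of two ligands
#'
#' Tanimoto coefficient |A and B| / |A or B| over the on-bits of the
#' path-based topological fingerprints.
#'
#' @param molA,molB `ligand_mol`.
#' @param n_bits,max_path fingerprint parameters.
#' @return similarity in [0, 1].
#' @export
ligand_similarity <- function(molA, molB, n_bits = 2048L, max_path = 7L) {
  a <- topological_fingerprint(molA, n_bits, max_path)
  b <- topological_fingerprint(molB, n_bits, max_path)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Global alignment sequence similarity
#'
#' Needleman-Wunsch global alignment with match score 1 and no mismatch or
#' gap penalties (the score then equals the longest-common-subsequence
#' length), normalized by the longer sequence length so the value is bounded
#' in [0, 1] and penalizes length mismatch.
#'
#' @param seqA,seqB one-letter amino-acid sequences.
#' @return similarity in [0, 1].
#' @export
sequence_similarity <- function(seqA, seqB) {
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("sequence_similarity: empty sequence")
  alpha <- sort(unique(strsplit(paste0(seqA, seqB), "")[[1]]))
  m <- diag(1, length(alpha))
  dimnames(m) <- list(alpha, alpha)
  sc <- Biostrings::pairwiseAlignment(seqA, seqB, type = "global",
                                      substitutionMatrix = m,
                                      gapOpening = 0, gapExtension = 0,
                                      scoreOnly = TRUE)
  sc / max(nchar(seqA), nchar(seqB))
}

#' Pairwise similarity matrices for a collection of complexes
#'
#' @param ids complex ids.
#' @param sequences named character vector of receptor sequences per id.
#' @param ligands named list of `ligand_mol` per id.
#' @return object of class `similarity_matrix`: list with `ids`,
#'   `protein_sim` and `ligand_sim` (symmetric, unit diagonal).
#' @export
similarity_matrix <- function(ids, sequences, ligands) {
  n <- length(ids)
  stopifnot(n >= 2, all(ids %in% names(sequences)), all(ids %in% names(ligands)))
  ps <- diag(1, n); ls <- diag(1, n)
  fps <- lapply(ligands[ids], topological_fingerprint)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ps[i, j] <- ps[j, i] <- sequence_similarity(sequences[[ids[i]]],
                                                  sequences[[ids[j]]])
      u <- length(union(fps[[i]], fps[[j]]))
      ls[i, j] <- ls[j, i] <- if (u == 0) 0 else
        length(intersect(fps[[i]], fps[[j]])) / u
    }
  }
  dimnames(ps) <- dimnames(ls) <- list(ids, ids)
  structure(list(ids = ids, protein_sim = ps, ligand_sim = ls),
            class = "similarity_matrix")
}

new_split_plan <- function(fold, scheme, seed = NA_integer_) {
  structure(list(fold = fold, scheme = scheme, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan (%s, seed %s): %s\n", x$scheme, x$seed,
              paste(sprintf("%s=%d", names(table(x$fold)), table(x$fold)),
                    collapse = ", ")))
  invisible(x)
}

#' Repeated random target-level splits
#'
#' Splits complexes (never poses) into training and test sets at the given
#' ratio; the whole operation is repeated `repeats` times. Test size is
#' `round(n / (ratio + 1))`.
#'
#' @param ids complex ids.
#' @param ratio train:test ratio (default 4, i.e. 4:1).
#' @param repeats number of independent splits (default 10).
#' @param seed RNG seed.
#' @return list of `split_plan`s with folds "train"/"test".
#' @export
random_split <- function(ids, ratio = 4, repeats = 10, seed = 1L) {
  n <- length(ids)
  if (n < ratio + 1) stop("random_split: need at least ", ratio + 1, " complexes")
  n_test <- round(n / (ratio + 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    test <- sample(ids, n_test)
    fold <- stats::setNames(ifelse(ids %in% test, "test", "train"), ids)
    new_split_plan(fold, "random", seed)
  })
}

#' Refined-core split: a fixed held-out core set
#'
#' @param ids all complex ids.
#' @param core_ids ids of the core (test) set; must be a proper subset.
#' @return `split_plan` with folds "train"/"test".
#' @export
refined_core_split <- function(ids, core_ids) {
  unknown <- setdiff(core_ids, ids)
  if (length(unknown) > 0)
    stop("refined_core_split: unknown core id(s): ",
         paste(unknown, collapse = ", "))
  if (length(setdiff(ids, core_ids)) == 0)
    stop("refined_core_split: training set would be empty")
  fold <- stats::setNames(ifelse(ids %in% core_ids, "test", "train"), ids)
  new_split_plan(fold, "refined_core")
}

# similarity linkage predicate between two complexes
ccv_linked <- function(psim, lsim, protein_thr = 0.5, protein_thr_similar = 0.3,
                       ligand_thr = 0.9) {
  psim >= protein_thr | (psim >= protein_thr_similar & lsim >= ligand_thr)
}

#' Threefold clustered cross-validation split
#'
#' Complexes are linked when their protein sequence similarity reaches 0.5,
#' or reaches 0.3 while the cognate ligands are similar (Tanimoto >= 0.9).
#' Connected components of the linkage graph (transitive closure) are
#' assigned whole to k folds by greedy largest-component-first balancing, so
#' no cross-fold pair can satisfy the linkage predicate. Ties between folds
#' are broken by fold index; components of equal size by their smallest
#' member id.
#'
#' @param sim `similarity_matrix`.
#' @param k number of folds (default 3).
#' @param protein_thr,protein_thr_similar,ligand_thr linkage thresholds.
#' @return `split_plan` with folds "fold1"... "foldk".
#' @export
clustered_cv_split <- function(sim, k = 3, protein_thr = 0.5,
                               protein_thr_similar = 0.3, ligand_thr = 0.9) {
  stopifnot(inherits(sim, "similarity_matrix"))
  n <- length(sim$ids)
  link <- ccv_linked(sim$protein_sim, sim$ligand_sim, protein_thr,
                     protein_thr_similar, ligand_thr)
  diag(link) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(link, mode = "undirected")
  comp <- igraph::components(g)$membership
  comp_members <- split(seq_len(n), comp)
  sizes <- vapply(comp_members, length, integer(1))
  first_id <- vapply(comp_members, function(m) min(sim$ids[m]), character(1))
  o <- order(-sizes, first_id)
  fold_of <- integer(n)
  load <- integer(k)
  for (ci in o) {
    target <- which.min(load)
    fold_of[comp_members[[ci]]] <- target
    load[target] <- load[target] + sizes[ci]
  }
  if (max(sizes) > ceiling(n / k))
    warning("clustered_cv_split: one component holds ", max(sizes), " of ", n,
            " complexes; achieved fold sizes ",
            paste(load, collapse = "/"))
  fold <- stats::setNames(paste0("fold", fold_of), sim$ids)
  new_split_plan(fold, "ccv")
}

#' Serialize / deserialize split plans as JSON
#' @param plan `split_plan` (or list of them).
#' @param path JSON file.
#' @export
write_split_plan <- function(plan, path) {
  plans <- if (inherits(plan, "split_plan")) list(plan) else plan
  jsonlite::write_json(lapply(plans, function(p)
    list(scheme = p$scheme, seed = p$seed, fold = as.list(p$fold))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @return list of `split_plan`.
#' @export
read_split_plan <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(p)
    new_split_plan(unlist(p$fold), p$scheme,
                   if (is.null(p$seed)) NA_integer_ else p$seed))
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
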