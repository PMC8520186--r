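#' Symmetry-corrected heavy-atom RMSD
#'
#' Minimum root-mean-square deviation between a docked pose and the crystal
#' reference over all graph automorphisms of the molecule, computed in place
#' (no superposition; docked and crystal poses share the receptor frame).
#' Atom mappings are enumerated as element-colored graph isomorphisms between
#' the two heavy-atom bond graphs (bond orders are ignored for coloring, so
#' the correction is robust to dialect-dependent bond-order perception).
#' When the number of mappings exceeds `max_mappings`, a distance-matrix
#' Hungarian assignment within element classes is used as a bounded-runtime
#' heuristic, with a warning.
#'
#' @param pose_mol,reference `ligand_mol` with identical heavy-atom formula
#'   and isomorphic bond graphs.
#' @param max_mappings cap on enumerated automorphisms.
#' @return RMSD in Angstrom; never larger than the identity-mapping RMSD
#'   when the identity is a valid mapping.
#' @export
symmetry_rmsd <- function(pose_mol, reference, max_mappings = 10000L) {
  stopifnot(inherits(pose_mol, "ligand_mol"), inherits(reference, "ligand_mol"))
  if (!identical(mol_formula(pose_mol), mol_formula(reference)))
    stop("symmetry_rmsd: heavy-atom formulas differ")
  A <- mol_coords(reference)
  B <- mol_coords(pose_mol)
  g_ref <- mol_graph(reference)
  g_pose <- mol_graph(pose_mol)
  col_ref <- as.integer(factor(reference$atoms$element,
                               levels = sort(unique(reference$atoms$element))))
  col_pose <- as.integer(factor(pose_mol$atoms$element,
                                levels = sort(unique(reference$atoms$element))))
  n_map <- igraph::count_isomorphisms(g_ref, g_pose, method = "vf2",
                                      vertex.color1 = col_ref,
                                      vertex.color2 = col_pose)
  if (n_map == 0) stop("symmetry_rmsd: bond graphs are not isomorphic")
  if (n_map > max_mappings) {
    warning("symmetry_rmsd: ", n_map, " mappings exceed the cap (",
            max_mappings, "); using Hungarian assignment within element classes")
    return(.element_class_assignment_rmsd(A, B, reference$atoms$element,
                                          pose_mol$atoms$element))
  }
  maps <- igraph::graph.get.isomorphisms.vf2(g_ref, g_pose,
                                             vertex.color1 = col_ref,
                                             vertex.color2 = col_pose)
  best <- Inf
  for (m in maps) {
    perm <- as.integer(m)  # reference atom k corresponds to pose atom perm[k]
    v <- mean(rowSums((A - B[perm, , drop = FALSE])^2))
    if (v < best) best <- v
  }
  sqrt(best)
}

# heuristic lower-bound match: optimal assignment per element class
.element_class_assignment_rmsd <- function(A, B, elA, elB) {
  total <- 0
  for (el in unique(elA)) {
    ia <- which(elA == el)
    ib <- which(elB == el)
    d2 <- outer(seq_along(ia), seq_along(ib), function(p, q) {
      rowSums((A[ia[p], , drop = FALSE] - B[ib[q], , drop = FALSE])^2)
    })
    assign <- hungarian_assignment(matrix(d2, length(ia)))
    total <- total + sum(d2[cbind(seq_along(ia), assign)])
  }
  sqrt(total / nrow(A))
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Shortest-augmenting-path implementation for square cost matrices; used as
#' the bounded-runtime fallback when automorphism enumeration is capped.
#'
#' @param cost square numeric matrix.
#' @return integer vector `a` with row i assigned to column `a[i]`.
#' @export
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row assigned to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  res <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) res[p[j]] <- j - 1L
  res
}

#' Label a pose from its RMSD
#'
#' A pose is near-native (positive) when its RMSD is strictly below the
#' cutoff; an RMSD exactly equal to the cutoff is negative.
#'
#' @param rmsd non-negative RMSD in Angstrom.
#' @param cutoff near-native cutoff in Angstrom (default 2.0).
#' @return "positive" or "negative" (vectorized).
#' @export
label_pose <- function(rmsd, cutoff = 2.0) {
  if (any(!is.finite(rmsd)) || any(rmsd < 0))
    stop("label_pose: rmsd must be finite and non-negative")
  ifelse(rmsd < cutoff, "positive", "negative")
}

#' Compute RMSDs and near-native labels for every pose of a set
#'
#' Crystal poses get RMSD 0 by definition. Errors from [symmetry_rmsd()] are
#' re-signalled with the pose index.
#'
#' @param pose_set `pose_set`.
#' @param cutoff near-native cutoff in Angstrom.
#' @return data.frame with one row per pose: complex_id, pose_id, dock_rank,
#'   is_crystal, rmsd, label.
#' @export
label_pose_set <- function(pose_set, cutoff = 2.0) {
  stopifnot(inherits(pose_set, "pose_set"))
  rows <- lapply(seq_along(pose_set$poses), function(k) {
    p <- pose_set$poses[[k]]
    r <- if (p$is_crystal) 0.0 else
      tryCatch(symmetry_rmsd(p$mol, pose_set$reference),
               error = function(e) stop("label_pose_set: pose ", k, ": ",
                                        conditionMessage(e)))
    data.frame(complex_id = pose_set$complex_id,
               pose_id = sprintf("%s_p%02d", pose_set$complex_id, k),
               dock_rank = if (is.null(p$dock_rank)) NA_integer_ else p$dock_rank,
               is_crystal = p$is_crystal, rmsd = r,
               label = label_pose(r, cutoff), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
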