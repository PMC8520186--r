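#' Ligand molecule container
#'
#' A `ligand_mol` holds the heavy-atom structure of one small molecule:
#' elements, 3D coordinates (Angstrom), formal charges, and the bond graph
#' with bond orders and aromatic flags. Hydrogens are never stored; attached
#' hydrogen counts are derived from implicit-valence completion where needed.
#' Ring membership and atom-level aromaticity are perceived from the bond
#' graph at construction time.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (formal charge, default 0).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2, 3) and optionally `aromatic` (logical). Bond order 4 on
#'   input is interpreted as aromatic order-1.5 per the SDF convention.
#' @param name optional molecule name.
#' @return object of class `ligand_mol`.
#' @export
ligand_mol <- function(atoms, bonds, name = "") {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms <- data.frame(element = as.character(atoms$element),
                      x = as.numeric(atoms$x), y = as.numeric(atoms$y),
                      z = as.numeric(atoms$z),
                      charge = if ("charge" %in% names(atoms)) as.integer(atoms$charge) else 0L,
                      stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (n == 0L) stop("ligand_mol: empty molecule")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("ligand_mol: non-finite coordinates")
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0),
                        aromatic = logical(0))
  } else {
    arom <- if ("aromatic" %in% names(bonds)) as.logical(bonds$aromatic) else bonds$order == 4
    ord <- as.numeric(bonds$order)
    ord[ord == 4] <- 1.5
    ord[arom & ord %in% c(1, 2, 3)] <- 1.5
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = ord, aromatic = arom)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("ligand_mol: bond index out of range")
    if (any(bonds$i == bonds$j)) stop("ligand_mol: self-bond")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("ligand_mol: duplicate bonds")
  }
  mol <- structure(list(atoms = atoms, bonds = bonds, name = name),
                   class = "ligand_mol")
  ring <- mol_ring_atoms(mol)
  mol$atoms$in_ring <- ring
  mol$atoms$aromatic <- mol_aromatic_atoms(mol)
  mol
}

#' @export
print.ligand_mol <- function(x, ...) {
  cat(sprintf("ligand_mol %s: %d heavy atoms, %d bonds (%s)\n",
              if (nzchar(x$name)) sQuote(x$name) else "", nrow(x$atoms),
              nrow(x$bonds), paste(sort(unique(x$atoms$element)), collapse = ",")))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

mol_coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' @keywords internal
mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds) > 0)
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  g
}

# atoms lying on a cycle: incident to at least one non-bridge edge
mol_ring_atoms <- function(mol) {
  n <- n_atoms(mol)
  if (nrow(mol$bonds) == 0) return(rep(FALSE, n))
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  keep <- setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
  ring <- rep(FALSE, n)
  ring[c(mol$bonds$i[keep], mol$bonds$j[keep])] <- TRUE
  ring
}

mol_aromatic_atoms <- function(mol) {
  n <- n_atoms(mol)
  ar <- rep(FALSE, n)
  if (nrow(mol$bonds) > 0) {
    ab <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
    ar[c(ab$i, ab$j)] <- TRUE
  }
  ar
}

# neighbor list over the heavy-atom bond graph
mol_neighbors <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

mol_is_connected <- function(mol) {
  igraph::is_connected(mol_graph(mol))
}

#' Heavy-atom molecular formula as a sorted element-count signature
#' @keywords internal
mol_formula <- function(mol) {
  tab <- table(mol$atoms$element)
  paste(names(tab), as.integer(tab), sep = "", collapse = " ")
}

# standard valences used for implicit-H completion on the heavy-atom graph
.default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1)

# per-atom sum of bond orders. Aromatic bonds contribute per-atom: 1.5 for
# carbon and 2-connected nitrogen (pyridine-type), 1.0 for oxygen, sulfur and
# 3-connected nitrogen (which donate a lone pair to the ring), matching the
# canonical valences of aromatic heteroatoms without requiring kekulized
# input. 2-connected aromatic N is taken as pyridine-type; pyrrole-type N-H
# is not distinguishable from heavy atoms alone and is a documented
# limitation.
mol_bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  if (nrow(mol$bonds) == 0) return(s)
  deg <- mol_degree(mol)
  el <- mol$atoms$element
  contrib <- function(atom, k) {
    if (!mol$bonds$aromatic[k]) return(mol$bonds$order[k])
    if (el[atom] %in% c("O", "S")) return(1.0)
    if (el[atom] == "N") return(if (deg[atom] >= 3) 1.0 else 1.5)
    1.5
  }
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    s[i] <- s[i] + contrib(i, k)
    s[j] <- s[j] + contrib(j, k)
  }
  s
}

mol_degree <- function(mol) {
  d <- integer(n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    d[mol$bonds$i[k]] <- d[mol$bonds$i[k]] + 1L
    d[mol$bonds$j[k]] <- d[mol$bonds$j[k]] + 1L
  }
  d
}

#' Implicit hydrogen counts from valence completion
#'
#' Attached hydrogens are the difference between the element's standard
#' valence (adjusted by formal charge for N+ and O-) and the rounded sum of
#' heavy-atom bond orders. Hypervalent centres (sulfone S, phosphate P,
#' nitro N) get zero.
#' @keywords internal
mol_implicit_h <- function(mol) {
  bos <- round(mol_bond_order_sum(mol))
  el <- mol$atoms$element
  dv <- .default_valence[el]
  dv[is.na(dv)] <- bos[is.na(dv)]  # unknown element: no implicit H
  dv <- dv + ifelse(el %in% c("N", "O", "S"), mol$atoms$charge, 0L)
  pmax(0, dv - bos)
}

#' Apply a rigid transform (rotation then translation) to a molecule
#' @param mol ligand_mol
#' @param R 3x3 rotation matrix
#' @param t length-3 translation
#' @return transformed ligand_mol
#' @export
transform_mol <- function(mol, R = diag(3), t = c(0, 0, 0)) {
  xyz <- mol_coords(mol) %*% t(R)
  mol$atoms$x <- xyz[, 1] + t[1]
  mol$atoms$y <- xyz[, 2] + t[2]
  mol$atoms$z <- xyz[, 3] + t[3]
  mol
}

#' Write ligand molecules to an SDF (V2000) file
#'
#' Aromatic bonds are written with bond type 4; formal charges use the
#' atom-block charge code so that a round trip through [read_ligand()]
#' preserves elements, coordinates, charges and bond topology.
#'
#' @param mols a `ligand_mol` or list of them.
#' @param path output file.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "ligand_mol")) mols <- list(mols)
  chg_code <- function(q) {
    code <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 0, `-1` = 5, `-2` = 6, `-3` = 7)
    unname(code[as.character(q)])
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    a <- mol$atoms; b <- mol$bonds
    writeLines(c(if (nzchar(mol$name)) mol$name else "mol", "  posepower", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element, chg_code(a$charge)), con)
    if (nrow(b) > 0) {
      bt <- ifelse(b$aromatic, 4L, as.integer(round(b$order)))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, bt), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
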