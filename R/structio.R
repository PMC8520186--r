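#' Read a receptor structure from a PDB file
#'
#' Parses ATOM records via \pkg{bio3d}, keeping heavy atoms only: HETATM
#' records, waters and hydrogens are dropped. Alternate locations are
#' resolved by keeping the first-listed copy of each atom. Chain sequences
#' are derived from the residue order of appearance; nonstandard residues
#' map to "X".
#'
#' @param path PDB file.
#' @return object of class `protein_structure` with `atoms` (data.frame:
#'   element, x, y, z, resname, resno, chain, atom_name) and `chains`
#'   (named character vector of one-letter sequences).
#' @export
read_protein <- function(path) {
  if (!file.exists(path)) stop("read_protein: file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop("read_protein: cannot parse ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  el <- a$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- substr(trimws(a$elety[miss]), 1, 1)
  a$element <- sub("^([A-Za-z]).*", "\\1", toupper(el))
  two <- toupper(el) %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN")
  a$element[two] <- paste0(substr(toupper(el[two]), 1, 1),
                           tolower(substr(el[two], 2, 2)))
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(a) == 0) stop("read_protein: no heavy protein atoms in ", path)
  # altloc: keep first-listed location of each (chain, residue, atom name)
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  a <- a[!duplicated(key), , drop = FALSE]
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
    stop("read_protein: non-finite coordinates in ", path)
  atoms <- data.frame(element = a$element, x = a$x, y = a$y, z = a$z,
                      resname = a$resid, resno = a$resno,
                      chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
                      atom_name = trimws(a$elety), stringsAsFactors = FALSE)
  protein_structure(atoms)
}

#' Construct a protein_structure from an atom table
#' @param atoms data.frame with element, x, y, z, resname, resno, chain,
#'   atom_name.
#' @return `protein_structure`
#' @export
protein_structure <- function(atoms) {
  stopifnot(all(c("element", "x", "y", "z", "resname", "resno", "chain",
                  "atom_name") %in% names(atoms)))
  if (nrow(atoms) == 0) stop("protein_structure: empty structure")
  chains <- vapply(split(atoms, atoms$chain), function(ch) {
    resid <- ch$resname[!duplicated(ch$resno)]
    aa1 <- suppressWarnings(bio3d::aa321(resid))
    aa1[is.na(aa1) | !aa1 %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
    paste(aa1, collapse = "")
  }, character(1))
  structure(list(atoms = atoms, chains = chains), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d heavy atoms, %d chain(s): %s\n",
              nrow(x$atoms), length(x$chains),
              paste(sprintf("%s (%d aa)", names(x$chains), nchar(x$chains)),
                    collapse = ", ")))
  invisible(x)
}

protein_coords <- function(prot) as.matrix(prot$atoms[, c("x", "y", "z")])

#' Concatenated one-letter sequence of a receptor (chains in order)
#' @param prot protein_structure
#' @return character scalar
#' @export
protein_sequence <- function(prot) paste(prot$chains, collapse = "")

.sdf_charge_codes <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                       `5` = -1L, `6` = -2L, `7` = -3L)

#' Read ligand molecules from an SDF or MOL2 file
#'
#' One `ligand_mol` per record, in file order (record order defines docking
#' rank downstream). Hydrogens are dropped; bonds are re-indexed onto the
#' heavy-atom set. SDF (V2000) is parsed via \pkg{ChemmineR}; bond type 4
#' marks aromatic bonds. MOL2 (TRIPOS) is parsed directly; SYBYL bond type
#' "ar" marks aromatic bonds and elements come from the leading token of the
#' SYBYL atom type.
#'
#' @param path SDF/MOL/MOL2 file.
#' @return list of `ligand_mol`.
#' @export
read_ligand <- function(path) {
  if (!file.exists(path)) stop("read_ligand: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mols <- if (ext == "mol2") read_mol2(path) else read_sdf(path)
  if (length(mols) == 0) stop("read_ligand: no molecules in ", path)
  for (k in seq_along(mols)) {
    if (nrow(mols[[k]]$bonds) == 0 && n_atoms(mols[[k]]) > 1)
      stop("read_ligand: record ", k, " of ", path,
           " has no bond block; connectivity is required")
    if (n_atoms(mols[[k]]) > 1 && !mol_is_connected(mols[[k]]))
      warning("read_ligand: record ", k, " has a disconnected heavy-atom graph")
  }
  mols
}

read_sdf <- function(path) {
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                   error = function(e) stop("read_ligand: cannot parse ", path,
                                            ": ", conditionMessage(e)))
  lapply(seq_along(sdfs@SDF), function(k) {
    sdf <- sdfs@SDF[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    chg <- if ("C6" %in% colnames(ab)) {
      unname(.sdf_charge_codes[as.character(ab[, "C6"])])
    } else rep(0L, nrow(ab))
    chg[is.na(chg)] <- 0L
    atoms <- data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        charge = chg, stringsAsFactors = FALSE)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) NULL else
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.numeric(bb[, 3]))
    strip_hydrogens(atoms, bonds, name = ChemmineR::sdfid(sdfs)[k])
  })
}

read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) stop("read_ligand: no TRIPOS MOLECULE record in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    sect <- function(tag) {
      i <- grep(paste0("^@<TRIPOS>", tag), blk)
      if (length(i) == 0) return(character(0))
      j <- grep("^@<TRIPOS>", blk)
      nxt <- j[j > i[1]]
      body <- blk[(i[1] + 1L):(if (length(nxt)) nxt[1] - 1L else length(blk))]
      trimws(body[nzchar(trimws(body)) & !startsWith(trimws(body), "#")])
    }
    aline <- sect("ATOM")
    if (length(aline) == 0) stop("read_ligand: MOL2 record ", k, " has no atoms")
    af <- do.call(rbind, strsplit(aline, "[[:space:]]+"))
    sybyl <- af[, 6]
    el0 <- sub("\\..*$", "", sybyl)
    el <- paste0(toupper(substr(el0, 1, 1)), tolower(substring(el0, 2)))
    atoms <- data.frame(element = el, x = as.numeric(af[, 3]),
                        y = as.numeric(af[, 4]), z = as.numeric(af[, 5]),
                        charge = 0L, stringsAsFactors = FALSE)
    bline <- sect("BOND")
    bonds <- NULL
    if (length(bline) > 0) {
      bf <- do.call(rbind, strsplit(bline, "[[:space:]]+"))
      bt <- bf[, 4]
      ord <- suppressWarnings(as.numeric(bt))
      ord[bt == "ar"] <- 4
      ord[bt == "am"] <- 1
      ord[is.na(ord)] <- 1
      bonds <- data.frame(i = as.integer(bf[, 2]), j = as.integer(bf[, 3]),
                          order = ord)
    }
    nm <- sect("MOLECULE")
    strip_hydrogens(atoms, bonds, name = if (length(nm)) nm[1] else "")
  })
}

# drop hydrogens and reindex bonds onto the heavy-atom subset
strip_hydrogens <- function(atoms, bonds, name = "") {
  keep <- !(atoms$element %in% c("H", "D"))
  idx <- cumsum(keep)
  atoms <- atoms[keep, , drop = FALSE]
  if (!is.null(bonds) && nrow(bonds) > 0) {
    bk <- keep[bonds$i] & keep[bonds$j]
    bonds <- bonds[bk, , drop = FALSE]
    bonds$i <- idx[bonds$i]
    bonds$j <- idx[bonds$j]
  }
  ligand_mol(atoms, bonds, name = name)
}

#' Build a pose set from a receptor, crystal reference and docked poses
#'
#' Docked poses receive `dock_rank` equal to their position in the docking
#' output. The crystal reference is appended as an extra pose (without rank)
#' only when `include_crystal = TRUE`, which is the training-set convention;
#' test sets are built without it. In cross-docking mode, poses flagged as
#' cross-native (crystal ligands transplanted into another receptor by
#' alignment) are never admitted. Poses whose heavy-atom formula differs
#' from the reference are rejected with their index.
#'
#' @param receptor `protein_structure`.
#' @param reference crystal `ligand_mol` in the receptor frame.
#' @param poses list of `ligand_mol` in docking-rank order (or a file path
#'   readable by [read_ligand()]).
#' @param complex_id,receptor_id identifiers.
#' @param program docking program tag.
#' @param mode "redock" or "crossdock".
#' @param include_crystal append the crystal pose (training convention).
#' @param cross_native optional logical vector flagging cross-native poses.
#' @param max_poses cap on docked poses per set (docking convention: 20).
#' @return object of class `pose_set`.
#' @export
assemble_pose_set <- function(receptor, reference, poses, complex_id,
                              receptor_id = complex_id, program = "synthetic",
                              mode = c("redock", "crossdock"),
                              include_crystal = FALSE, cross_native = NULL,
                              max_poses = 20L) {
  mode <- match.arg(mode)
  stopifnot(inherits(receptor, "protein_structure"),
            inherits(reference, "ligand_mol"))
  if (is.character(poses)) poses <- read_ligand(poses)
  if (inherits(poses, "ligand_mol")) poses <- list(poses)
  if (length(poses) == 0) stop("assemble_pose_set: no docked poses supplied")
  ref_formula <- mol_formula(reference)
  for (k in seq_along(poses)) {
    if (!identical(mol_formula(poses[[k]]), ref_formula))
      stop("assemble_pose_set: pose ", k,
           " heavy-atom formula differs from the reference (",
           mol_formula(poses[[k]]), " vs ", ref_formula, ")")
  }
  keep <- rep(TRUE, length(poses))
  if (!is.null(cross_native)) {
    stopifnot(length(cross_native) == length(poses))
    if (mode == "crossdock" && any(cross_native)) {
      message("assemble_pose_set: excluding ", sum(cross_native),
              " cross-native pose(s)")
      keep <- !cross_native
    }
  }
  ranks <- seq_along(poses)[keep]
  poses <- poses[keep]
  if (length(poses) == 0) stop("assemble_pose_set: all poses excluded")
  if (length(poses) > max_poses) {
    warning("assemble_pose_set: keeping the first ", max_poses, " of ",
            length(poses), " docked poses")
    poses <- poses[seq_len(max_poses)]
    ranks <- ranks[seq_len(max_poses)]
  }
  plist <- Map(function(mol, r) {
    list(mol = mol, dock_rank = r, source = program, is_crystal = FALSE)
  }, poses, ranks)
  if (include_crystal) {
    plist <- c(plist, list(list(mol = reference, dock_rank = NA_integer_,
                                source = "crystal", is_crystal = TRUE)))
  }
  structure(list(complex_id = complex_id, receptor_id = receptor_id,
                 receptor = receptor, reference = reference,
                 poses = plist, mode = mode),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("pose_set %s (%s): %d poses (%d crystal), receptor %d atoms\n",
              x$complex_id, x$mode, length(x$poses),
              sum(vapply(x$poses, `[[`, logical(1), "is_crystal")),
              nrow(x$receptor$atoms)))
  invisible(x)
}

#' Read a docking-run metadata table
#'
#' CSV with columns complex_id, receptor_id, ligand_file, reference_file,
#' receptor_file, program, mode. Relative file paths are resolved against
#' the directory of the metadata file.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("complex_id", "receptor_id", "ligand_file", "reference_file",
            "receptor_file", "program", "mode")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0)
    stop("read_metadata: missing columns: ", paste(miss, collapse = ", "))
  base <- dirname(path)
  for (col in c("ligand_file", "reference_file", "receptor_file")) {
    rel <- !grepl("^(/|[A-Za-z]:)", md[[col]])
    md[[col]][rel] <- file.path(base, md[[col]][rel])
  }
  md
}

#' Load pose sets described by a metadata table
#' @param metadata data.frame from [read_metadata()] (or its path).
#' @param include_crystal append crystal poses (training convention).
#' @return list of `pose_set`.
#' @export
load_pose_sets <- function(metadata, include_crystal = FALSE) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  receptors <- new.env()
  lapply(seq_len(nrow(metadata)), function(r) {
    row <- metadata[r, ]
    key <- row$receptor_file
    if (is.null(receptors[[key]])) receptors[[key]] <- read_protein(key)
    assemble_pose_set(receptors[[key]],
                      read_ligand(row$reference_file)[[1]],
                      read_ligand(row$ligand_file),
                      complex_id = row$complex_id,
                      receptor_id = row$receptor_id,
                      program = row$program, mode = row$mode,
                      include_crystal = include_crystal)
  })
}
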