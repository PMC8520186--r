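#' Amino-acid residue templates in peptide context
#'
#' Heavy-atom connectivity templates for the 20 canonical amino acids as they
#' occur mid-chain in a polypeptide: the backbone nitrogen carries one extra
#' heavy neighbour (the preceding carbonyl carbon) and the carbonyl carbon
#' one extra (the following nitrogen). Attached-hydrogen counts and formal
#' charges are part of the template (they are chemical ground truth for
#' amino acids); side-chain protonation follows physiological pH: lysine and
#' arginine cationic, aspartate/glutamate anionic.
#'
#' Beyond the 20 canonical templates, variants whose connectivity types
#' differ are included for vocabulary derivation: the three histidine
#' protonation states (delta/epsilon tautomers and the doubly protonated
#' imidazolium) and both kekulizations of the resonance-delocalized arginine
#' guanidinium. Variant templates carry the canonical residue name in
#' `resname` with a distinguishing suffix in the list name.
#'
#' @return named list of templates; each has `resname`, `atoms`
#'   (data.frame: name, element, nH, charge, aromatic, ring, extra_heavy)
#'   and `bonds` (data.frame: a, b, order over atom names).
#' @export
amino_acid_templates <- function() {
  # atoms: "name element nH charge aromatic ring extra"
  res <- function(resname, side_atoms, side_bonds, bb_n_h = 1L, bb_n_ring = FALSE,
                  ca_ring = FALSE, ca_h = 1L) {
    bb <- data.frame(
      name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      nH = c(bb_n_h, ca_h, 0L, 0L), charge = 0L,
      aromatic = FALSE, ring = c(bb_n_ring, ca_ring, FALSE, FALSE),
      extra_heavy = c(1L, 0L, 1L, 0L), stringsAsFactors = FALSE)
    bonds <- data.frame(a = c("N", "CA", "C"), b = c("CA", "C", "O"),
                        order = c(1, 1, 2), stringsAsFactors = FALSE)
    if (!is.null(side_atoms)) {
      bb <- rbind(bb, side_atoms)
      bonds <- rbind(bonds, side_bonds)
    }
    list(resname = resname, atoms = bb, bonds = bonds)
  }
  at <- function(...) {
    # each argument: "NAME EL nH charge ar ring"
    f <- do.call(rbind, lapply(list(...), function(s) strsplit(s, " +")[[1]]))
    data.frame(name = f[, 1], element = f[, 2], nH = as.integer(f[, 3]),
               charge = as.integer(f[, 4]), aromatic = f[, 5] == "1",
               ring = f[, 6] == "1", extra_heavy = 0L, stringsAsFactors = FALSE)
  }
  bd <- function(...) {
    f <- do.call(rbind, lapply(list(...), function(s) strsplit(s, " +")[[1]]))
    data.frame(a = f[, 1], b = f[, 2], order = as.numeric(f[, 3]),
               stringsAsFactors = FALSE)
  }
  ch2 <- function(nm) sprintf("%s C 2 0 0 0", nm)
  ch3 <- function(nm) sprintf("%s C 3 0 0 0", nm)
  arC <- function(nm, nH) sprintf("%s C %d 0 1 1", nm, nH)

  t <- list()
  t$ALA <- res("ALA", at(ch3("CB")), bd("CA CB 1"))
  t$GLY <- res("GLY", NULL, NULL, ca_h = 2L)
  t$SER <- res("SER", at(ch2("CB"), "OG O 1 0 0 0"), bd("CA CB 1", "CB OG 1"))
  t$CYS <- res("CYS", at(ch2("CB"), "SG S 1 0 0 0"), bd("CA CB 1", "CB SG 1"))
  t$THR <- res("THR", at("CB C 1 0 0 0", "OG1 O 1 0 0 0", ch3("CG2")),
               bd("CA CB 1", "CB OG1 1", "CB CG2 1"))
  t$VAL <- res("VAL", at("CB C 1 0 0 0", ch3("CG1"), ch3("CG2")),
               bd("CA CB 1", "CB CG1 1", "CB CG2 1"))
  t$LEU <- res("LEU", at(ch2("CB"), "CG C 1 0 0 0", ch3("CD1"), ch3("CD2")),
               bd("CA CB 1", "CB CG 1", "CG CD1 1", "CG CD2 1"))
  t$ILE <- res("ILE", at("CB C 1 0 0 0", ch2("CG1"), ch3("CG2"), ch3("CD1")),
               bd("CA CB 1", "CB CG1 1", "CB CG2 1", "CG1 CD1 1"))
  t$MET <- res("MET", at(ch2("CB"), ch2("CG"), "SD S 0 0 0 0", ch3("CE")),
               bd("CA CB 1", "CB CG 1", "CG SD 1", "SD CE 1"))
  t$PRO <- res("PRO",
               at("CB C 2 0 0 1", "CG C 2 0 0 1", "CD C 2 0 0 1"),
               bd("CA CB 1", "CB CG 1", "CG CD 1", "CD N 1"),
               bb_n_h = 0L, bb_n_ring = TRUE, ca_ring = TRUE)
  t$PHE <- res("PHE",
               at(ch2("CB"), "CG C 0 0 1 1", arC("CD1", 1), arC("CD2", 1),
                  arC("CE1", 1), arC("CE2", 1), arC("CZ", 1)),
               bd("CA CB 1", "CB CG 1", "CG CD1 1.5", "CG CD2 1.5",
                  "CD1 CE1 1.5", "CD2 CE2 1.5", "CE1 CZ 1.5", "CE2 CZ 1.5"))
  t$TYR <- res("TYR",
               at(ch2("CB"), "CG C 0 0 1 1", arC("CD1", 1), arC("CD2", 1),
                  arC("CE1", 1), arC("CE2", 1), "CZ C 0 0 1 1", "OH O 1 0 0 0"),
               bd("CA CB 1", "CB CG 1", "CG CD1 1.5", "CG CD2 1.5",
                  "CD1 CE1 1.5", "CD2 CE2 1.5", "CE1 CZ 1.5", "CE2 CZ 1.5",
                  "CZ OH 1"))
  t$TRP <- res("TRP",
               at(ch2("CB"), "CG C 0 0 1 1", arC("CD1", 1), "NE1 N 1 0 1 1",
                  "CD2 C 0 0 1 1", "CE2 C 0 0 1 1", arC("CE3", 1),
                  arC("CZ2", 1), arC("CZ3", 1), arC("CH2", 1)),
               bd("CA CB 1", "CB CG 1", "CG CD1 1.5", "CD1 NE1 1.5",
                  "NE1 CE2 1.5", "CE2 CD2 1.5", "CD2 CG 1.5", "CD2 CE3 1.5",
                  "CE3 CZ3 1.5", "CZ3 CH2 1.5", "CH2 CZ2 1.5", "CZ2 CE2 1.5"))
  t$ASP <- res("ASP", at(ch2("CB"), "CG C 0 0 0 0", "OD1 O 0 0 0 0",
                         "OD2 O 0 -1 0 0"),
               bd("CA CB 1", "CB CG 1", "CG OD1 2", "CG OD2 1"))
  t$GLU <- res("GLU", at(ch2("CB"), ch2("CG"), "CD C 0 0 0 0", "OE1 O 0 0 0 0",
                         "OE2 O 0 -1 0 0"),
               bd("CA CB 1", "CB CG 1", "CG CD 1", "CD OE1 2", "CD OE2 1"))
  t$ASN <- res("ASN", at(ch2("CB"), "CG C 0 0 0 0", "OD1 O 0 0 0 0",
                         "ND2 N 2 0 0 0"),
               bd("CA CB 1", "CB CG 1", "CG OD1 2", "CG ND2 1"))
  t$GLN <- res("GLN", at(ch2("CB"), ch2("CG"), "CD C 0 0 0 0", "OE1 O 0 0 0 0",
                         "NE2 N 2 0 0 0"),
               bd("CA CB 1", "CB CG 1", "CG CD 1", "CD OE1 2", "CD NE2 1"))
  t$LYS <- res("LYS", at(ch2("CB"), ch2("CG"), ch2("CD"), ch2("CE"),
                         "NZ N 3 1 0 0"),
               bd("CA CB 1", "CB CG 1", "CG CD 1", "CD CE 1", "CE NZ 1"))
  # arginine, guanidinium kekulized with the double bond on NH1 (+)
  t$ARG <- res("ARG", at(ch2("CB"), ch2("CG"), ch2("CD"), "NE N 1 0 0 0",
                         "CZ C 0 0 0 0", "NH1 N 2 1 0 0", "NH2 N 2 0 0 0"),
               bd("CA CB 1", "CB CG 1", "CG CD 1", "CD NE 1", "NE CZ 1",
                  "CZ NH1 2", "CZ NH2 1"))
  # epsilon tautomer is the canonical histidine template
  t$HIS <- res("HIS", at(ch2("CB"), "CG C 0 0 1 1", "ND1 N 0 0 1 1",
                         arC("CD2", 1), arC("CE1", 1), "NE2 N 1 0 1 1"),
               bd("CA CB 1", "CB CG 1", "CG ND1 1.5", "CG CD2 1.5",
                  "ND1 CE1 1.5", "CD2 NE2 1.5", "CE1 NE2 1.5"))

  # variants that enlarge the connectivity-type vocabulary
  v <- t$HIS
  v$atoms$nH[v$atoms$name == "ND1"] <- 1L
  v$atoms$nH[v$atoms$name == "NE2"] <- 0L
  t$HIS_HID <- v
  v <- t$HIS
  v$atoms$nH[v$atoms$name == "ND1"] <- 1L
  v$atoms$charge[v$atoms$name == "ND1"] <- 1L
  t$HIS_HIP <- v
  # arginine with the guanidinium double bond on NE (+)
  v <- t$ARG
  v$atoms[v$atoms$name == "NE", c("nH", "charge")] <- list(1L, 1L)
  v$atoms[v$atoms$name == "NH1", c("nH", "charge")] <- list(2L, 0L)
  v$bonds$order[v$bonds$a == "NE" & v$bonds$b == "CZ"] <- 2
  v$bonds$order[v$bonds$a == "CZ" & v$bonds$b == "NH1"] <- 1
  t$ARG_NE <- v
  t
}

# standard valence of protein elements; formal charge adds to it
.protein_valence <- c(C = 4, N = 3, O = 2, S = 2)

ecif_key <- function(element, valence, heavy, nH, aromatic, ring) {
  sprintf("%s;%d;%d;%d;%d;%d", element, as.integer(valence), as.integer(heavy),
          as.integer(nH), as.integer(aromatic), as.integer(ring))
}

# type every atom of one template
template_types <- function(tpl) {
  a <- tpl$atoms
  deg <- a$extra_heavy
  for (k in seq_len(nrow(tpl$bonds))) {
    ia <- match(tpl$bonds$a[k], a$name); ib <- match(tpl$bonds$b[k], a$name)
    deg[ia] <- deg[ia] + 1L
    deg[ib] <- deg[ib] + 1L
  }
  val <- .protein_valence[a$element] + a$charge
  ecif_key(a$element, val, deg, a$nH, a$aromatic, a$ring)
}

#' Derive the ECIF protein atom-type vocabulary from residue templates
#'
#' Types every heavy atom of every amino-acid template (including the
#' protonation/tautomer/resonance variants) with the connectivity key
#' `Element;Valence;HeavyNeighbors;AttachedH;IsAromatic;IsInRing` and returns
#' the sorted set of distinct types over the protein element alphabet
#' C, N, O, S. With the shipped templates the set has exactly 22 members.
#'
#' @param templates list from [amino_acid_templates()].
#' @return character vector of distinct ECIF type keys.
#' @export
derive_protein_type_vocabulary <- function(templates = amino_acid_templates()) {
  if (length(templates) == 0) stop("no templates supplied")
  keys <- unlist(lapply(templates, template_types), use.names = FALSE)
  el <- sub(";.*", "", keys)
  sort(unique(keys[el %in% c("C", "N", "O", "S")]))
}

#' Per-atom annotations for receptor featurization
#'
#' Lookup table mapping (residue name, atom name) to the atom's ECIF protein
#' type and its Vina interaction classes: hydrophobic (carbon with no bonded
#' N/O/S), hydrogen-bond donor (N/O with at least one hydrogen) and acceptor
#' (any N/O). Built from the canonical template of each residue; peptide-bond
#' neighbours are included in the neighbour-element sets.
#'
#' @return data.frame with columns resname, atom_name, element, ecif_type,
#'   hydrophobic, donor, acceptor.
#' @export
protein_atom_annotations <- function() {
  cached("protein_annotations", .protein_atom_annotations)
}

.protein_atom_annotations <- function() {
  tpls <- amino_acid_templates()
  tpls <- tpls[!grepl("_", names(tpls))]  # canonical forms only
  out <- lapply(tpls, function(tpl) {
    a <- tpl$atoms
    types <- template_types(tpl)
    nb_el <- lapply(seq_len(nrow(a)), function(i) {
      els <- character(0)
      for (k in seq_len(nrow(tpl$bonds))) {
        if (tpl$bonds$a[k] == a$name[i]) els <- c(els, a$element[match(tpl$bonds$b[k], a$name)])
        if (tpl$bonds$b[k] == a$name[i]) els <- c(els, a$element[match(tpl$bonds$a[k], a$name)])
      }
      # peptide context: N sees the preceding carbonyl C, C the following N
      if (a$name[i] == "N") els <- c(els, "C")
      if (a$name[i] == "C") els <- c(els, "N")
      els
    })
    data.frame(resname = tpl$resname, atom_name = a$name, element = a$element,
               ecif_type = types,
               hydrophobic = a$element == "C" &
                 !vapply(nb_el, function(e) any(e %in% c("N", "O", "S")), logical(1)),
               donor = a$element %in% c("N", "O") & a$nH > 0,
               acceptor = a$element %in% c("N", "O"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
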