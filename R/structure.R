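# Structure model: atoms + network nodes (residues and ligand molecules).

#' Construct a structure model
#'
#' A `structure_model` holds the atom table and reference coordinates of a
#' molecular system, plus the derived network node table. Polymer residues are
#' one node each; every non-water HETATM residue (ATP, an allosteric
#' modulator, ...) is a single ligand node aggregating all of its heavy atoms.
#' Waters are expected to have been discarded upstream.
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `resno`
#'   (author residue number), `resname`, `chain`, `is_polymer` (logical),
#'   one row per atom.
#' @param xyz numeric vector of length `3 * nrow(atoms)` (x1,y1,z1,x2,...) or
#'   an `nrow(atoms) x 3` matrix of reference coordinates in Angstrom.
#' @return object of class `structure_model` with components:
#'   \describe{
#'     \item{atoms}{atom table with `node` (integer node id) and `is_heavy`}
#'     \item{nodes}{node table: `id`, `label`, `kind` ("residue"/"ligand"),
#'       `chain`, `seq` (sequence position used by the separation rule; `NA`
#'       for ligand nodes)}
#'     \item{xyz}{reference coordinates as a length-3N numeric vector}
#'   }
#' @export
structure_model <- function(atoms, xyz) {
  req <- c("atom_name", "element", "resno", "resname", "chain", "is_polymer")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stopf("atoms is missing columns: %s", paste(miss, collapse = ", "))
  if (is.matrix(xyz)) xyz <- as.numeric(t(xyz))
  if (length(xyz) != 3L * nrow(atoms)) stopf("xyz length must be 3 * n_atoms")

  atoms$element <- toupper(atoms$element)
  atoms$is_heavy <- atoms$element != "H"

  # residue nodes in order of first appearance, then ligand nodes
  rkey <- paste(atoms$chain, atoms$resno, atoms$resname)
  poly <- atoms$is_polymer
  pkeys <- unique(rkey[poly])
  lkeys <- unique(rkey[!poly])
  node_of_key <- stats::setNames(seq_along(c(pkeys, lkeys)), c(pkeys, lkeys))
  atoms$node <- as.integer(node_of_key[rkey])

  first <- !duplicated(rkey)
  fo <- order(atoms$node[first])
  fa <- atoms[first, ][fo, ]
  # seq: residue number within the chain (operand of the i to i+n separation
  # rule); author numbering so chain gaps keep their true distance
  seqpos <- ifelse(fa$is_polymer, as.integer(fa$resno), NA_integer_)
  nodes <- data.frame(
    id = fa$node,
    label = paste0(fa$resname, fa$resno),
    kind = ifelse(fa$is_polymer, "residue", "ligand"),
    chain = fa$chain,
    seq = seqpos,
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, nodes = nodes, xyz = as.numeric(xyz)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- sum(x$nodes$kind == "residue")
  nlig <- sum(x$nodes$kind == "ligand")
  cat(sprintf("structure_model: %d atoms (%d heavy), %d residues, %d ligand node(s)\n",
              nrow(x$atoms), sum(x$atoms$is_heavy), nres, nlig))
  invisible(x)
}

water_resnames <- c("HOH", "WAT", "TIP3", "SOL", "DOD")

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records via \code{bio3d::read.pdb}. Waters are
#' discarded; remaining HETATM residues become single ligand nodes. Missing
#' element symbols are inferred from the atom name (with a warning). For
#' alternate locations only the first conformer is kept.
#'
#' @param path PDB file.
#' @return [structure_model()]; if the file holds several MODEL records the
#'   model is built from the first and the full coordinate set is attached as
#'   attribute `"frames"` (a [frame_set()]).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- !(at$resid %in% water_resnames)
  if (!any(keep)) stopf("no non-water atoms in %s", path)
  at <- at[keep, ]
  ele <- at$elesy
  bad <- is.na(ele) | ele == ""
  if (any(bad)) {
    warning("element column missing for ", sum(bad), " atom(s); inferring from atom name")
    ele[bad] <- element_from_name(at$elety[bad])
  }
  atoms <- data.frame(
    atom_name = at$elety,
    element = toupper(trimws(ele)),
    resno = at$resno,
    resname = at$resid,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    is_polymer = at$type == "ATOM",
    stringsAsFactors = FALSE
  )
  xyz_all <- pdb$xyz
  if (is.matrix(xyz_all)) {
    cidx <- as.numeric(t(cbind((which(keep) - 1) * 3 + 1,
                               (which(keep) - 1) * 3 + 2,
                               (which(keep) - 1) * 3 + 3)))
    xyz_all <- xyz_all[, cidx, drop = FALSE]
    model <- structure_model(atoms, xyz_all[1, ])
    if (nrow(xyz_all) > 1) {
      attr(model, "frames") <- frame_set(xyz_all, label = basename(path))
    }
    model
  } else {
    structure_model(atoms, xyz_all)
  }
}

#' @noRd
element_from_name <- function(name) {
  nm <- gsub("[0-9' ]", "", name)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA_"), two, one)
}

#' Write a structure (with optional per-node B-factor values) to PDB
#'
#' Used to color residues by community id in molecular viewers: the value
#' mapped to each node is written into the B-factor column of its atoms.
#'
#' @param model [structure_model()].
#' @param file output path.
#' @param node_values optional named numeric vector (names = node ids).
#' @export
write_structure_pdb <- function(model, file, node_values = NULL) {
  b <- rep(0, nrow(model$atoms))
  if (!is.null(node_values)) {
    v <- node_values[as.character(model$atoms$node)]
    b <- ifelse(is.na(v), 0, as.numeric(v))
  }
  at <- model$atoms
  bio3d::write.pdb(
    file = file, xyz = model$xyz,
    type = ifelse(at$is_polymer, "ATOM", "HETATM"),
    resno = at$resno, resid = at$resname, eleno = seq_len(nrow(at)),
    elety = at$atom_name, chain = at$chain, elesy = at$element, b = b
  )
  invisible(file)
}

#' Atom indices of the protein backbone (N, CA, C, O)
#'
#' Heavy backbone atoms of polymer residues; the default selection for
#' superposition and RMSF in line with common practice for kinase ensembles.
#'
#' @param model [structure_model()].
#' @return integer atom indices.
#' @export
select_backbone <- function(model) {
  at <- model$atoms
  which(at$is_polymer & at$is_heavy & at$atom_name %in% c("N", "CA", "C", "O"))
}
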