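# Molecular-graph layer on top of OpenBabel (via ChemmineOB).
#
# SMILES strings are parsed into a light kekulized graph representation
# (element symbols plus a bond table with integer orders) on which the
# scaffold machinery operates. Charges and stereochemistry are deliberately
# not carried into this layer: scaffold identity is a 2-D ring-topology
# concept, so scaffolds are compared after stripping both. Full-fidelity
# canonicalization of input SMILES goes through canonicalize_smiles(),
# which is a plain OpenBabel round-trip and preserves charge and stereo.

# typed conditions -----------------------------------------------------------

stop_bitter <- function(class, message, ...) {
  stop(structure(class = c(paste0("bitterspace_", class), "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Canonicalization is
#' idempotent and maps any two SMILES of the same molecular graph to the
#' same string.
#'
#' @param smiles character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))   # identical output
#' @export
canonicalize_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  if (any(is.na(smiles) | !nzchar(smiles))) {
    stop_bitter("parse_error", "NA or empty SMILES string",
                smiles = smiles[is.na(smiles) | !nzchar(smiles)])
  }
  inp <- paste0(smiles, "\t", seq_along(smiles), collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(inp, "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- rep(NA_character_, length(smiles))
  for (p in parts) {
    if (length(p) >= 2) res[as.integer(p[2])] <- p[1]
  }
  # the converter aborts a batch at the first bad entry; retry stragglers
  # one at a time so only genuine parse failures are reported
  for (i in which(is.na(res))) {
    one <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[i], "\tx\n")),
      error = function(e) "")
    if (nzchar(one)) res[i] <- strsplit(one, "\t", fixed = TRUE)[[1]][1]
  }
  if (anyNA(res)) {
    stop_bitter("parse_error",
                sprintf("unparseable SMILES: %s",
                        paste(smiles[is.na(res)], collapse = ", ")),
                smiles = smiles[is.na(res)])
  }
  res
}

#' Check which SMILES strings parse
#'
#' Validation is per molecule (the converter aborts a batch at the first
#' invalid entry, so batching cannot attribute failures).
#'
#' @param smiles character vector.
#' @return logical vector, TRUE where the string parses to a valid molecule.
#' @export
smiles_parses <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\tx\n")),
      error = function(e) "")
    nzchar(out)
  }, logical(1), USE.NAMES = FALSE)
}

# internal graph representation ----------------------------------------------

# A bitter_mol is a list:
#   elem : character vector of element symbols (implicit hydrogens not listed)
#   bonds: data.frame(a1, a2, order) with 1-based atom indices
#   orig : original atom indices in the molecule this fragment came from
new_mol <- function(elem, bonds, orig = seq_along(elem)) {
  structure(list(elem = elem, bonds = bonds, orig = orig), class = "bitter_mol")
}

empty_mol <- function() {
  new_mol(character(0),
          data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)),
          integer(0))
}

n_atoms <- function(mol) length(mol$elem)

#' Parse a SMILES string into a molecular graph
#'
#' Parses and sanitizes one SMILES string via OpenBabel and returns the
#' kekulized heavy-atom graph (element symbols and a bond table with integer
#' bond orders). Charges and stereochemistry are stripped; this
#' representation feeds the scaffold machinery only.
#'
#' @param smiles a single SMILES string.
#' @return An object of class `bitter_mol`.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\tm\n")),
    error = function(e) "")
  if (!nzchar(txt)) {
    stop_bitter("parse_error", sprintf("unparseable SMILES: %s", smiles),
                smiles = smiles)
  }
  mol_from_molblock(txt)
}

# fixed-width V2000 molblock -> graph (atom elements + bond table)
mol_from_molblock <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stop_bitter("parse_error", "empty molecule")
  alines <- lines[5:(4 + na)]
  elem <- trimws(substr(alines, 32, 34))
  if (nb > 0) {
    blines <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(a1 = as.integer(substr(blines, 1, 3)),
                        a2 = as.integer(substr(blines, 4, 6)),
                        order = as.integer(substr(blines, 7, 9)))
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  new_mol(elem, bonds)
}

# Minimal V2000 MOL block for a fragment graph; coordinates zeroed, charges
# absent (stripped by design), implicit hydrogens re-perceived on read.
mol_to_molblock <- function(mol, title = "frag") {
  n <- n_atoms(mol)
  m <- nrow(mol$bonds)
  head <- c(title, "  bitterspace", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, mol$elem)
  bonds <- character(0)
  if (m > 0) {
    bonds <- sprintf("%3d%3d%3d  0  0  0  0",
                     mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  }
  paste(c(head, atoms, bonds, "M  END"), collapse = "\n")
}

# Canonical SMILES for a list of fragment graphs, in one batched OpenBabel
# call (titles carry the index so partial failures realign).
canonical_fragments <- function(mols) {
  if (length(mols) == 0) return(character(0))
  blocks <- vapply(seq_along(mols),
                   function(i) mol_to_molblock(mols[[i]], title = as.character(i)),
                   character(1))
  txt <- paste0(paste(blocks, collapse = "\n$$$$\n"), "\n$$$$\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_character_, length(mols))
  for (p in strsplit(lines, "\t", fixed = TRUE)) {
    if (length(p) >= 2) res[as.integer(p[2])] <- p[1]
  }
  res
}

#' Molecular weight from SMILES
#'
#' Average molecular weight (standard atomic masses, implicit hydrogens
#' included), in g/mol.
#'
#' @param smiles character vector of SMILES strings.
#' @return Numeric vector of molecular weights.
#' @examples
#' molecular_weight("C")   # methane, 16.04
#' @export
molecular_weight <- function(smiles) {
  vapply(smiles, function(s) {
    if (!smiles_parses(s)) {
      stop_bitter("parse_error", sprintf("unparseable SMILES: %s", s), smiles = s)
    }
    ref <- ChemmineOB::forEachMol("SMILES", paste0(s, "\tx"), identity)
    as.numeric(ChemmineOB::prop_OB(ref)$MW)
  }, numeric(1), USE.NAMES = FALSE)
}

# graph utilities -------------------------------------------------------------

mol_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  }
  g
}

# Logical vector over bonds: TRUE if the bond lies on a cycle (not a bridge).
ring_bond_mask <- function(mol) {
  if (nrow(mol$bonds) == 0) return(logical(0))
  g <- mol_igraph(mol)
  br <- as.integer(igraph::bridges(g))
  mask <- rep(TRUE, nrow(mol$bonds))
  mask[br] <- FALSE
  mask
}

# Induced subgraph on a set of atom indices (bonds with both ends kept).
induced_mol <- function(mol, atoms) {
  atoms <- sort(atoms)
  if (length(atoms) == 0) return(empty_mol())
  idx <- match(seq_len(n_atoms(mol)), atoms)
  keep <- !is.na(idx[mol$bonds$a1]) & !is.na(idx[mol$bonds$a2])
  bonds <- data.frame(a1 = idx[mol$bonds$a1[keep]],
                      a2 = idx[mol$bonds$a2[keep]],
                      order = mol$bonds$order[keep])
  new_mol(mol$elem[atoms], bonds, orig = mol$orig[atoms])
}

mol_is_connected <- function(mol) {
  if (n_atoms(mol) <= 1) return(n_atoms(mol) == 1)
  igraph::is_connected(mol_igraph(mol))
}
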