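# Bemis-Murcko frameworks and the all-orders scaffold network.
#
# The framework of a molecule is the union of its ring systems and the
# acyclic linker paths connecting them, obtained by iteratively pruning
# terminal (degree-1) atoms; exocyclic atoms attached to a retained atom by a
# double or triple bond (e.g. a carbonyl oxygen on a ring) are kept, per the
# original Bemis-Murcko definition. The scaffold network of a molecule is
# the set of all sub-frameworks reachable from the full framework by
# repeatedly deleting one terminal ring system (a ring system attached to
# the rest through a single linker attachment) and re-pruning, over all
# deletion orders, deduplicated by canonical SMILES. Because any cycle of
# ring systems through linkers would itself be a ring, the quotient graph of
# ring systems is always a tree, and the network equals the set of
# frameworks induced by connected subsets of ring systems.

# Atom indices (into `mol`) of the framework: 2-core (iterated leaf pruning)
# plus exocyclic multi-bonded atoms hanging off it.
framework_atoms <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0 || nrow(mol$bonds) == 0) return(integer(0))
  if (!any(ring_bond_mask(mol))) return(integer(0))
  alive <- rep(TRUE, n)
  repeat {
    deg <- tabulate(c(mol$bonds$a1[alive[mol$bonds$a1] & alive[mol$bonds$a2]],
                      mol$bonds$a2[alive[mol$bonds$a1] & alive[mol$bonds$a2]]),
                    nbins = n)
    leaves <- alive & deg <= 1
    if (!any(leaves)) break
    alive[leaves] <- FALSE
  }
  core <- which(alive)
  # re-attach exocyclic double/triple-bonded terminal atoms
  multi <- mol$bonds$order >= 2
  a1in <- mol$bonds$a1 %in% core
  a2in <- mol$bonds$a2 %in% core
  extra <- c(mol$bonds$a2[multi & a1in & !a2in],
             mol$bonds$a1[multi & !a1in & a2in])
  sort(unique(c(core, extra)))
}

#' Bemis-Murcko framework of a molecule
#'
#' Extracts the molecular framework: all ring systems plus the acyclic
#' linkers connecting them, with terminal side chains pruned. Exocyclic
#' atoms double- or triple-bonded to a retained ring or linker atom (such as
#' a carbonyl oxygen) are kept. Acyclic molecules have an empty framework.
#' The operation is idempotent.
#'
#' @param x a SMILES string or a `bitter_mol` graph.
#' @return Canonical SMILES of the framework for SMILES input (`""` for an
#'   acyclic molecule), or a `bitter_mol` fragment for graph input.
#' @examples
#' murcko_framework("Cc1ccccc1")   # toluene -> benzene
#' murcko_framework("CCCCCC")      # acyclic -> ""
#' @export
murcko_framework <- function(x) {
  if (is.character(x)) {
    mol <- parse_smiles(x)
    fr <- induced_mol(mol, framework_atoms(mol))
    if (n_atoms(fr) == 0) return("")
    return(canonical_fragments(list(fr)))
  }
  stopifnot(inherits(x, "bitter_mol"))
  induced_mol(x, framework_atoms(x))
}

# Ring systems of a framework graph: connected components over ring bonds.
# Fused, bridged and spiro rings share atoms and therefore fall into one
# system. Returns a list of atom-index vectors (indices into `fr`).
ring_systems <- function(fr) {
  mask <- ring_bond_mask(fr)
  if (!any(mask)) return(list())
  g <- igraph::make_empty_graph(n = n_atoms(fr), directed = FALSE)
  g <- igraph::add_edges(g, rbind(fr$bonds$a1[mask], fr$bonds$a2[mask]))
  comp <- igraph::components(g)
  ring_atoms <- which(tabulate(c(fr$bonds$a1[mask], fr$bonds$a2[mask]),
                               nbins = n_atoms(fr)) > 0)
  split(ring_atoms, comp$membership[ring_atoms])
}

#' Scaffold network of a molecule
#'
#' Enumerates all canonical scaffolds reachable from the full Bemis-Murcko
#' framework by repeatedly deleting one terminal ring system and re-pruning
#' to a valid framework, over all deletion orders, deduplicated by canonical
#' SMILES. The full framework is always a member; a single-ring molecule
#' yields exactly its one ring; an acyclic molecule yields the empty set.
#'
#' @param smiles a single SMILES string.
#' @return Character vector of canonical scaffold SMILES (the `ScaffoldSet`),
#'   possibly empty.
#' @examples
#' scaffold_network("C(c1ccccc1)c1ccccc1")  # diphenylmethane: itself + benzene
#' @export
scaffold_network <- function(smiles) {
  mol <- parse_smiles(smiles)
  f0 <- induced_mol(mol, framework_atoms(mol))
  if (n_atoms(f0) == 0) return(character(0))
  seen <- new.env(parent = emptyenv())
  frags <- list()
  stack <- list(f0)
  while (length(stack) > 0) {
    f <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- paste(sort(f$orig), collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    frags[[length(frags) + 1L]] <- f
    sys <- ring_systems(f)
    if (length(sys) > 1) {
      for (s in sys) {
        rest <- setdiff(seq_len(n_atoms(f)), s)
        f2 <- induced_mol(f, rest)
        f2 <- induced_mol(f2, framework_atoms(f2))
        if (n_atoms(f2) > 0 && mol_is_connected(f2)) {
          stack[[length(stack) + 1L]] <- f2
        }
      }
    }
  }
  smi <- canonical_fragments(frags)
  sort(unique(smi[!is.na(smi)]))
}

#' Unique scaffolds of a compound set
#'
#' Union of the scaffold networks of all compounds, deduplicated by
#' canonical scaffold SMILES. Acyclic compounds contribute nothing;
#' duplicate compounds contribute nothing beyond their first occurrence.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional compound identifiers used in parse-error messages.
#' @return Character vector of canonical scaffold SMILES.
#' @export
unique_scaffolds <- function(smiles, ids = NULL) {
  if (length(smiles) == 0) return(character(0))
  out <- character(0)
  for (i in seq_along(smiles)) {
    net <- tryCatch(scaffold_network(smiles[i]), bitterspace_parse_error = function(e) {
      id <- if (!is.null(ids)) ids[i] else smiles[i]
      stop_bitter("parse_error", sprintf("compound %s: %s", id, conditionMessage(e)))
    })
    out <- c(out, net)
  }
  sort(unique(out))
}

#' Scaffold-per-compound ratio
#'
#' Number of unique scaffolds of a receptor's agonist set divided by the
#' number of agonists, rounded half-up to 2 decimals. Values above one
#' indicate chemically complex ligands (more scaffolds than compounds);
#' values below one indicate scaffold sharing.
#'
#' @param n_scaffolds unique scaffold count.
#' @param n_compounds agonist count, at least 1.
#' @return Ratio rounded to 2 decimals.
#' @examples
#' scaffold_per_compound(9, 1)   # 9.00
#' scaffold_per_compound(52, 9)  # 5.78
#' @export
scaffold_per_compound <- function(n_scaffolds, n_compounds) {
  if (any(n_compounds < 1)) {
    stop_bitter("domain_error", "scaffold-per-compound undefined for 0 compounds")
  }
  round_half_up(n_scaffolds / n_compounds, 2)
}

# round-half-up, the display convention used for ratios and median MW
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
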