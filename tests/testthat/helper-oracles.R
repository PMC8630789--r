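# Independent oracles.
#
# brute_scaffolds enumerates the scaffold network by a different route than
# the package (which recursively deletes terminal ring systems): it tries
# every one of the 2^k - 1 non-empty subsets of ring systems, prunes the
# induced subgraph back to a framework, and keeps the connected results.
# The two enumerations share only the low-level graph/canonicalization
# primitives, whose behavior is pinned by their own unit tests.

brute_scaffolds <- function(smiles) {
  mol <- bitterspace:::parse_smiles(smiles)
  fr <- bitterspace:::induced_mol(mol, bitterspace:::framework_atoms(mol))
  if (bitterspace:::n_atoms(fr) == 0) return(character(0))
  sys <- bitterspace:::ring_systems(fr)
  k <- length(sys)
  frags <- list()
  for (m in seq_len(2^k - 1)) {
    pick <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
    drop <- unlist(sys[-pick])
    keep <- setdiff(seq_len(bitterspace:::n_atoms(fr)), drop)
    sub <- bitterspace:::induced_mol(fr, keep)
    f2 <- bitterspace:::induced_mol(sub, bitterspace:::framework_atoms(sub))
    if (bitterspace:::n_atoms(f2) > 0 && bitterspace:::mol_is_connected(f2) &&
        length(bitterspace:::ring_systems(f2)) == length(pick)) {
      frags[[length(frags) + 1L]] <- f2
    }
  }
  smi <- bitterspace:::canonical_fragments(frags)
  sort(unique(smi[!is.na(smi)]))
}

# a random non-canonical SMILES of the same molecule, by permuting atom
# numbering and rewriting the mol block
renumbered_smiles <- function(smiles) {
  mol <- bitterspace:::parse_smiles(smiles)
  n <- bitterspace:::n_atoms(mol)
  perm <- sample.int(n)
  inv <- order(perm)
  mol2 <- bitterspace:::new_mol(
    mol$elem[perm],
    data.frame(a1 = inv[mol$bonds$a1], a2 = inv[mol$bonds$a2],
               order = mol$bonds$order))
  out <- ChemmineOB::convertFormat(
    "SDF", "SMI", paste0(bitterspace:::mol_to_molblock(mol2, "p"), "\n$$$$\n"))
  strsplit(out, "\t", fixed = TRUE)[[1]][1]
}

# run a short python snippet and return its stdout lines
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  system2("python", f, stdout = TRUE)
}
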