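# Fixtures are built in code: small compound sets with known scaffolds and
# hand-computable statistics.

toy_compounds <- function() {
  data.frame(
    compound_id = c("c1", "c2", "c3", "c4", "c5"),
    name = c("toluene", "ethylbenzene", "hexane", "cyclohexanone", "pyridine"),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "CCCCCC", "O=C1CCCCC1", "c1ccncc1"),
    superclass = c("Benzenoids", "Benzenoids", "Lipids and lipid-like molecules",
                   "Organic oxygen compounds", NA),
    is_food = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    tested_all_receptors = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

toy_activation <- function() {
  act <- matrix(0L, 5, 3, dimnames = list(NULL, c("TAS2R14", "TAS2R39", "TAS2R47")))
  act[1, ] <- c(1L, 1L, 0L)
  act[2, ] <- c(1L, 0L, 0L)
  act[3, ] <- c(0L, 1L, 1L)
  act[4, ] <- c(0L, 0L, 1L)
  act[5, ] <- c(1L, 1L, 1L)
  act
}

toy_dataset <- function() activity_dataset(toy_compounds(), toy_activation())

write_toy_csv <- function(path, n = 3) {
  df <- cbind(toy_compounds()[seq_len(n), ],
              as.data.frame(toy_activation()[seq_len(n), 1:2, drop = FALSE]))
  write.csv(df, path, row.names = FALSE)
  path
}

# plain Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  sa <- outer(a, a, "==")
  sb <- outer(b, b, "==")
  up <- upper.tri(sa)
  mean(sa[up] == sb[up])
}
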