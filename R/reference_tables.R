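# Packaged reference tables: the published per-receptor counts of the
# curated food bitter-compound collection, and the receptor lists of the
# four most promiscuous food bitterants. These printed tables are inputs to
# the arithmetic stages (ratio and promiscuity recomputation) and supply the
# default activation probabilities of the synthetic generator.

#' Published per-receptor counts of the curated food agonist collection
#'
#' Per-receptor agonist counts, unique-scaffold counts and median molecular
#' weights of the curated food bitter-compound collection (17 receptors with
#' at least one agonist; compound total 133). The scaffold-per-compound
#' ratio is deliberately not stored: it is recomputed by
#' [scaffold_per_compound()].
#'
#' @return data.frame with columns `receptor`, `n_compounds`,
#'   `n_unique_scaffolds`, `median_mw`.
#' @export
food_agonist_reference_counts <- function() {
  utils::read.csv(system.file("extdata", "tas2r_food_agonist_counts.csv",
                              package = "bitterspace"),
                  stringsAsFactors = FALSE)
}

#' The four most promiscuous food bitterants and their receptors
#'
#' Structures (canonical SMILES) and published receptor lists of quinine,
#' amarogentin, epigallocatechin gallate (EGCG) and caffeine.
#'
#' @return data.frame with columns `compound`, `smiles` and `receptors`
#'   (list column of receptor name vectors).
#' @export
promiscuous_agonist_reference <- function() {
  df <- utils::read.csv(system.file("extdata", "promiscuous_agonists.csv",
                                    package = "bitterspace"),
                        stringsAsFactors = FALSE)
  df$receptors <- strsplit(df$receptors, ";", fixed = TRUE)
  df
}

#' Build an activity dataset from the promiscuous-agonist reference lists
#'
#' Expands the packaged receptor lists of the four promiscuous bitterants
#' into an `activity_dataset`, so compound promiscuity can be recomputed
#' from the activation matrix rather than read off. The lists are reported
#' as printed: counts are dataset-relative and receptors outside the
#' 17-receptor food table (e.g. TAS2R9 for caffeine) are kept as-is.
#'
#' @return An `activity_dataset` with 4 compounds.
#' @export
promiscuous_agonist_dataset <- function() {
  ref <- promiscuous_agonist_reference()
  act <- matrix(0L, nrow(ref), length(tas2r_universe()),
                dimnames = list(ref$compound, tas2r_universe()))
  for (i in seq_len(nrow(ref))) act[i, resolve_receptor(ref$receptors[[i]])] <- 1L
  activity_dataset(
    data.frame(compound_id = ref$compound, name = ref$compound,
               smiles = ref$smiles, superclass = NA_character_,
               is_food = TRUE, tested_all_receptors = TRUE),
    act)
}
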