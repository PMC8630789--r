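# Receptor and compound promiscuity statistics, the per-receptor summary
# table, and the receptor x superclass association matrix.

#' Receptor promiscuity index
#'
#' Fraction of the dataset's compounds that activate a receptor: the number
#' of agonists of the receptor divided by the total number of molecules in
#' the dataset. A broadly tuned receptor has a high index.
#'
#' @param ds an `activity_dataset`.
#' @param receptor a receptor name/alias, or `NULL` for all 25 receptors.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
receptor_promiscuity_index <- function(ds, receptor = NULL) {
  if (n_compounds(ds) == 0) stop_bitter("validation_error", "empty dataset")
  idx <- colSums(ds$activation) / n_compounds(ds)
  if (is.null(receptor)) return(idx)
  idx[resolve_receptor(receptor)]
}

#' Scaffold promiscuity index
#'
#' Number of unique scaffolds of a receptor's agonist set divided by an
#' explicit total unique-scaffold count. The denominator is an argument
#' because the reference total may come from a larger compound set than the
#' numerators (the convention used when profiling the all-TAS2R-tested
#' subset against the scaffold total of the full food set).
#'
#' @param ds an `activity_dataset`.
#' @param receptor receptor name or alias.
#' @param total_unique_scaffolds positive denominator.
#' @return Fraction in `[0, 1]` (0 for a receptor with no agonists).
#' @export
scaffold_promiscuity_index <- function(ds, receptor, total_unique_scaffolds) {
  if (total_unique_scaffolds < 1) {
    stop_bitter("validation_error", "total_unique_scaffolds must be >= 1")
  }
  r <- resolve_receptor(receptor)
  ag <- ds$activation[, r] == 1
  if (!any(ag)) return(0)
  length(unique_scaffolds(ds$compounds$smiles[ag], ds$compounds$compound_id[ag])) /
    total_unique_scaffolds
}

#' Compound promiscuity
#'
#' Number of distinct receptors each compound activates (activation row
#' sum).
#'
#' @param ds an `activity_dataset`.
#' @param compound_id one compound id, or `NULL` for all compounds.
#' @return Named integer vector of receptor counts.
#' @export
compound_promiscuity <- function(ds, compound_id = NULL) {
  counts <- rowSums(ds$activation)
  if (is.null(compound_id)) return(counts)
  if (!all(compound_id %in% ds$compounds$compound_id)) {
    stop_bitter("validation_error",
                sprintf("unknown compound: %s",
                        paste(setdiff(compound_id, ds$compounds$compound_id),
                              collapse = ", ")))
  }
  counts[compound_id]
}

#' Promiscuity bin of a compound
#'
#' Maps a receptor count to the promiscuity groups used for flow
#' aggregation: compounds activating one, two, three, four, or at least
#' `boundary` receptors. Counts of zero are rejected (an agonist dataset
#' contains only agonists).
#'
#' @param n integer vector of receptor counts (>= 1).
#' @param boundary lower edge of the open top bin (default 5, giving bins
#'   1, 2, 3, 4, 5+).
#' @return Factor with ordered levels `"1"`, ..., `"<boundary>+"`.
#' @examples
#' promiscuity_bin(c(1, 4, 9))
#' @export
promiscuity_bin <- function(n, boundary = 5) {
  if (any(n < 1)) stop_bitter("domain_error", "receptor count must be >= 1 (not an agonist)")
  levs <- c(as.character(seq_len(boundary - 1)), paste0(boundary, "+"))
  lab <- ifelse(n >= boundary, paste0(boundary, "+"), as.character(n))
  factor(lab, levels = levs, ordered = TRUE)
}

#' Per-receptor summary table
#'
#' One row per receptor with at least one agonist: agonist count, unique
#' scaffold count of the agonist set, scaffold-per-compound ratio (2
#' decimals), and median molecular weight (median of an even-sized set is
#' the mean of the central pair; displayed rounded to the nearest integer).
#'
#' @param ds an `activity_dataset`.
#' @return data.frame with columns `receptor`, `n_compounds`,
#'   `n_unique_scaffolds`, `scaffold_per_compound`, `median_mw`.
#' @export
receptor_summary_table <- function(ds) {
  counts <- colSums(ds$activation)
  active <- names(counts)[counts > 0]
  mw <- if (n_compounds(ds) > 0) molecular_weight(ds$compounds$smiles) else numeric(0)
  rows <- lapply(active, function(r) {
    ag <- ds$activation[, r] == 1
    nsc <- length(unique_scaffolds(ds$compounds$smiles[ag],
                                   ds$compounds$compound_id[ag]))
    data.frame(receptor = r,
               n_compounds = sum(ag),
               n_unique_scaffolds = nsc,
               scaffold_per_compound = scaffold_per_compound(nsc, sum(ag)),
               median_mw = round_half_up(stats::median(mw[ag])))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(receptor = character(0), n_compounds = integer(0),
               n_unique_scaffolds = integer(0),
               scaffold_per_compound = numeric(0), median_mw = numeric(0))
  rownames(out) <- NULL
  out
}

#' Receptor-by-superclass association counts
#'
#' Entry (r, s) counts the compounds of superclass s that activate receptor
#' r; one compound activating three receptors contributes three counts.
#' Compounds with a missing superclass are excluded with a warning.
#'
#' @param ds an `activity_dataset`.
#' @return Integer matrix, receptors (with >= 1 counted agonist) x
#'   superclasses.
#' @export
superclass_receptor_matrix <- function(ds) {
  has_sc <- !is.na(ds$compounds$superclass)
  if (!all(has_sc)) {
    warning(sprintf("%d compound(s) without superclass excluded", sum(!has_sc)))
  }
  act <- ds$activation[has_sc, , drop = FALSE]
  sc <- ds$compounds$superclass[has_sc]
  classes <- sort(unique(sc))
  m <- t(vapply(tas2r_universe(), function(r) {
    vapply(classes, function(s) sum(act[sc == s, r]), numeric(1))
  }, numeric(length(classes))))
  colnames(m) <- classes
  storage.mode(m) <- "integer"
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Write a summary table to CSV
#'
#' Column order follows the per-receptor summary convention (compounds,
#' scaffolds, ratio, median MW). `decimal_mark = ","` is offered for
#' comparison against sources printing comma decimals.
#'
#' @param tab data.frame from [receptor_summary_table()].
#' @param path output path.
#' @param decimal_mark `"."` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(tab, path, decimal_mark = ".") {
  if (decimal_mark == ",") {
    utils::write.csv2(tab, path, row.names = FALSE, quote = TRUE)
  } else {
    utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}
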