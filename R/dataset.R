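# ActivityDataset: the central container. Compound metadata plus a binary
# compound x receptor activation matrix over the fixed 25-receptor universe.

#' Construct an activity dataset
#'
#' Bundles compound records with a binary compound-by-receptor activation
#' matrix. The receptor universe is fixed at the 25 human TAS2Rs: columns
#' for receptors absent from `activation` are added as all-zero, so
#' promiscuity denominators never drift with file contents.
#'
#' @param compounds data.frame with columns `compound_id`, `name`, `smiles`,
#'   `superclass` (may be `NA`), `is_food`, `tested_all_receptors`.
#' @param activation binary matrix (one row per compound); column names are
#'   receptor names or aliases.
#' @return An object of class `activity_dataset`.
#' @export
activity_dataset <- function(compounds, activation) {
  stopifnot(is.data.frame(compounds))
  req <- c("compound_id", "name", "smiles", "superclass", "is_food",
           "tested_all_receptors")
  miss <- setdiff(req, names(compounds))
  if (length(miss) > 0) {
    stop_bitter("format_error",
                sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")))
  }
  compounds <- compounds[req]
  compounds$compound_id <- as.character(compounds$compound_id)
  if (anyDuplicated(compounds$compound_id)) {
    stop_bitter("validation_error",
                sprintf("duplicate compound_id: %s",
                        paste(unique(compounds$compound_id[duplicated(compounds$compound_id)]),
                              collapse = ", ")))
  }
  universe <- tas2r_universe()
  act <- matrix(0L, nrow(compounds), length(universe),
                dimnames = list(compounds$compound_id, universe))
  if (!is.null(activation) && ncol(as.matrix(activation)) > 0 && nrow(compounds) > 0) {
    activation <- as.matrix(activation)
    if (nrow(activation) != nrow(compounds)) {
      stop_bitter("validation_error", "activation rows do not match compounds")
    }
    prim <- resolve_receptor(colnames(activation))
    if (anyDuplicated(prim)) {
      stop_bitter("validation_error",
                  sprintf("receptor columns resolve to the same primary name: %s",
                          paste(unique(prim[duplicated(prim)]), collapse = ", ")))
    }
    vals <- suppressWarnings(as.integer(activation))
    if (anyNA(vals) || !all(vals %in% c(0L, 1L))) {
      stop_bitter("validation_error", "activation entries must be 0/1")
    }
    act[, prim] <- matrix(vals, nrow(activation), ncol(activation))
  }
  structure(list(compounds = compounds, receptors = universe, activation = act),
            class = "activity_dataset")
}

#' @export
print.activity_dataset <- function(x, ...) {
  cat(sprintf("<activity_dataset> %d compounds x %d receptors (%d receptors with >=1 agonist)\n",
              nrow(x$compounds), length(x$receptors), sum(colSums(x$activation) > 0)))
  invisible(x)
}

#' Number of compounds in a dataset
#' @param ds an `activity_dataset`.
#' @return integer.
#' @export
n_compounds <- function(ds) nrow(ds$compounds)

#' Read a compound-receptor activity table
#'
#' Reads a CSV with the compound metadata columns (`compound_id`, `name`,
#' `smiles`, `superclass`, `is_food`, `tested_all_receptors`) and any number
#' of 0/1 receptor columns (primary TAS2R names or their documented
#' aliases). Rows whose SMILES do not parse are rejected and collected into
#' an error report attached as attribute `"rejected"`, never silently
#' dropped.
#'
#' @param path path to a CSV file.
#' @return An `activity_dataset`; `attr(, "rejected")` is a data.frame of
#'   rejected rows with a `reason` column.
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop_bitter("io_error", sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("compound_id", "name", "smiles", "superclass", "is_food",
            "tested_all_receptors")
  miss <- setdiff(meta, names(df))
  if (length(miss) > 0) {
    stop_bitter("format_error",
                sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")))
  }
  rcols <- setdiff(names(df), meta)
  bad_rcols <- rcols[!is_receptor_name(rcols)]
  if (length(bad_rcols) > 0) {
    stop_bitter("validation_error",
                sprintf("unresolvable receptor column(s): %s",
                        paste(bad_rcols, collapse = ", ")))
  }
  ok <- smiles_parses(df$smiles)
  rejected <- df[!ok, meta, drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- "unparseable SMILES"
  df <- df[ok, , drop = FALSE]
  df$superclass <- ifelse(is.na(df$superclass) | !nzchar(df$superclass),
                          NA_character_, df$superclass)
  df$is_food <- as.logical(df$is_food)
  df$tested_all_receptors <- as.logical(df$tested_all_receptors)
  act <- if (length(rcols) > 0) as.matrix(df[rcols]) else NULL
  ds <- activity_dataset(df[meta], act)
  attr(ds, "rejected") <- rejected
  ds
}

#' Write an activity dataset to CSV
#'
#' Writes the compound metadata followed by the 25 receptor columns, in a
#' machine-stable dialect (comma separator, `.` decimal, UTF-8). The
#' written file reads back to an identical dataset.
#'
#' @param ds an `activity_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(ds, path) {
  out <- cbind(ds$compounds, as.data.frame(ds$activation, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset an activity dataset
#'
#' Selects compounds by a named criterion or an arbitrary predicate.
#' Receptor columns are always preserved (the receptor universe is fixed),
#' so a subset of a subset equals the conjunction of criteria.
#'
#' @param ds an `activity_dataset`.
#' @param criterion `"food"` (rows flagged `is_food`), `"all_tested"` (rows
#'   flagged `tested_all_receptors`), `"classified"` (rows with a known
#'   superclass: neither missing nor `"Unclassified"`), `"all"`, or a
#'   predicate `function(compounds)` returning a logical vector.
#' @return An `activity_dataset` containing exactly the matching rows; an
#'   empty selection returns an empty dataset with a warning.
#' @export
select_subset <- function(ds, criterion = "all") {
  keep <- if (is.function(criterion)) {
    criterion(ds$compounds)
  } else {
    switch(match.arg(criterion, c("all", "food", "all_tested", "classified")),
           all = rep(TRUE, n_compounds(ds)),
           food = ds$compounds$is_food,
           all_tested = ds$compounds$tested_all_receptors,
           classified = !is.na(ds$compounds$superclass) &
                        ds$compounds$superclass != "Unclassified")
  }
  keep <- !is.na(keep) & keep
  if (!any(keep)) warning("select_subset: empty result")
  structure(list(compounds = ds$compounds[keep, , drop = FALSE],
                 receptors = ds$receptors,
                 activation = ds$activation[keep, , drop = FALSE]),
            class = "activity_dataset")
}
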