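#' The 25 human bitter taste receptors
#'
#' Returns the fixed universe of human TAS2R names used throughout the
#' package. Promiscuity denominators and activation-matrix columns are always
#' defined over this universe, regardless of which receptor columns a given
#' input file happens to contain.
#'
#' @return Character vector of length 25, in numeric order of the TAS2R
#'   nomenclature.
#' @export
tas2r_universe <- function() {
  paste0("TAS2R", c(1, 3, 4, 5, 7, 8, 9, 10, 13, 14, 16, 19, 20, 30, 31,
                    38, 39, 40, 41, 42, 43, 45, 46, 50, 60))
}

# Alternative receptor names -> primary names. Restricted to the alias pairs
# documented for this receptor family; each alias resolves to exactly one
# primary name.
.tas2r_aliases <- c(
  TAS2R48 = "TAS2R19",
  TAS2R49 = "TAS2R20", TAS2R56 = "TAS2R20",
  TAS2R47 = "TAS2R30",
  TAS2R44 = "TAS2R31", TAS2R53 = "TAS2R31",
  TAS2R61 = "TAS2R38",
  TAS2R57 = "TAS2R39",
  TAS2R58 = "TAS2R40",
  TAS2R52 = "TAS2R43",
  TAS2R54 = "TAS2R46",
  TAS2R51 = "TAS2R50"
)

#' Resolve TAS2R receptor names and aliases to primary names
#'
#' Alternative names (e.g. `"TAS2R47"`) are mapped onto their primary TAS2R
#' name (`"TAS2R30"`). Matching is case-insensitive and tolerates a `hTAS2R`
#' prefix and surrounding whitespace.
#'
#' @param x character vector of receptor names or aliases.
#' @return Character vector of primary TAS2R names.
#' @examples
#' resolve_receptor(c("TAS2R47", "tas2r14"))
#' @export
resolve_receptor <- function(x) {
  key <- toupper(trimws(as.character(x)))
  key <- sub("^HTAS2R", "TAS2R", key)
  out <- ifelse(key %in% names(.tas2r_aliases), .tas2r_aliases[key], key)
  bad <- !(out %in% tas2r_universe())
  if (any(bad)) {
    stop_bitter("validation_error",
                sprintf("unresolvable receptor name(s): %s",
                        paste(unique(x[bad]), collapse = ", ")))
  }
  unname(out)
}

#' Test whether strings name a TAS2R receptor (primary or alias)
#' @param x character vector.
#' @return logical vector.
#' @export
is_receptor_name <- function(x) {
  key <- sub("^HTAS2R", "TAS2R", toupper(trimws(as.character(x))))
  key %in% c(tas2r_universe(), names(.tas2r_aliases))
}
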