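# Public 166-key MACCS structural fingerprints, evaluated by SMARTS matching
# against the packaged key dictionary, plus the similarity/distance layer
# feeding the t-SNE embedding.

.bitter_env <- new.env(parent = emptyenv())

maccs_keys <- function() {
  if (is.null(.bitter_env$maccs)) {
    path <- system.file("extdata", "maccs166_smarts.tsv", package = "bitterspace")
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]  # '#' is SMARTS syntax, not comment
    .bitter_env$maccs <- utils::read.delim(text = paste(lines, collapse = "\n"),
                                           quote = "", stringsAsFactors = FALSE)
  }
  .bitter_env$maccs
}

# aromatic SSSR ring count approximated by unique matches of small
# all-aromatic ring SMARTS (5-7 membered), for MACCS key 125
count_aromatic_rings <- function(molref) {
  pats <- c("[a]1[a][a][a][a]1", "[a]1[a][a][a][a][a]1", "[a]1[a][a][a][a][a][a]1")
  sum(vapply(pats, function(p)
    as.numeric(ChemmineOB::smartsSearch_OB(molref, p, uniqueMatches = TRUE)),
    numeric(1)))
}

count_fragments <- function(smiles) {
  mol <- parse_smiles(smiles)
  if (n_atoms(mol) <= 1) return(n_atoms(mol))
  igraph::count_components(mol_igraph(mol))
}

#' MACCS structural-key fingerprint
#'
#' Computes the public 166-bit MACCS key fingerprint of each molecule: bit
#' i is set iff the molecule matches substructure pattern i of the packaged
#' public key dictionary (with the per-key minimum match counts). Keys that
#' are not single SMARTS patterns are computed from the molecular graph:
#' key 1 (isotope, always 0 for the plain SMILES inputs used here), key 125
#' (more than one aromatic ring) and key 166 (more than one fragment).
#'
#' @param smiles character vector of SMILES strings.
#' @return An integer matrix with one row per molecule and 166 columns;
#'   rownames are the input SMILES names if present.
#' @examples
#' fp <- maccs_fingerprint(c("C", "c1ccccc1"))
#' rowSums(fp)   # methane sets (almost) no keys
#' @export
maccs_fingerprint <- function(smiles) {
  keys <- maccs_keys()
  out <- matrix(0L, length(smiles), 166)
  if (!is.null(names(smiles))) rownames(out) <- names(smiles)
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (!smiles_parses(s)) {
      stop_bitter("parse_error", sprintf("unparseable SMILES: %s", s), smiles = s)
    }
    ref <- ChemmineOB::forEachMol("SMILES", paste0(s, "\tx"), identity)
    for (k in seq_len(nrow(keys))) {
      pat <- keys$smarts[k]
      if (pat == "?") next
      nm <- tryCatch(as.numeric(
        ChemmineOB::smartsSearch_OB(ref, pat, uniqueMatches = TRUE)),
        error = function(e) 0)
      if (nm > keys$min_over[k]) out[i, keys$key[k]] <- 1L
    }
    if (count_aromatic_rings(ref) > 1) out[i, 125] <- 1L
    if (count_fragments(s) > 1) out[i, 166] <- 1L
  }
  out
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection-over-union of two equal-length bit vectors; defined as 1
#' when both vectors are all-zero.
#'
#' @param a,b binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0), c(0, 1, 1))  # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop_bitter("validation_error", "fingerprint length mismatch")
  }
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Pairwise distance matrix over fingerprints
#'
#' Euclidean distance on the raw bits (the default; on 0/1 vectors this is
#' the square root of the Hamming distance) or Jaccard distance
#' (1 - Tanimoto).
#'
#' @param fps fingerprint matrix, one row per molecule.
#' @param metric `"euclidean"` or `"jaccard"`.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(fps, metric = c("euclidean", "jaccard")) {
  metric <- match.arg(metric)
  fps <- as.matrix(fps)
  if (nrow(fps) < 2) stop_bitter("validation_error", "need at least 2 fingerprints")
  D <- if (metric == "euclidean") {
    as.matrix(stats::dist(fps, method = "euclidean"))
  } else {
    n <- nrow(fps)
    inter <- tcrossprod(fps)
    ones <- rowSums(fps)
    un <- outer(ones, ones, "+") - inter
    sim <- ifelse(un == 0, 1, inter / ifelse(un == 0, 1, un))
    1 - sim
  }
  dimnames(D) <- list(rownames(fps), rownames(fps))
  diag(D) <- 0
  D
}
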