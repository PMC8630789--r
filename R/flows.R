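# Alluvial flow aggregation: receptor -> superclass -> promiscuity bin.
#
# Two different accounting conventions coexist by design: the
# receptor -> superclass edges count (compound, receptor-activation) pairs,
# because one compound really does flow into every receptor it activates;
# the superclass -> bin edges count each compound once. The two layer totals
# therefore differ, and both are recorded in the graph metadata.

#' Build the alluvial flow graph
#'
#' Aggregates an activity dataset into a weighted tripartite flow graph with
#' receptors on the left (sorted by descending promiscuity index, ties by
#' name), superclasses in the middle (sorted by descending compound count,
#' ties by name) and promiscuity bins on the right (ascending). Compounds
#' without a superclass label are excluded (with a warning) before
#' aggregation.
#'
#' @param ds an `activity_dataset`.
#' @param bin_boundary lower edge of the open top promiscuity bin.
#' @return An object of class `flow_graph`: list with `nodes` (data.frame
#'   `id`, `layer`, `label`, `order`), `links` (data.frame `source`,
#'   `target`, `value`) and `meta`.
#' @export
alluvial_flows <- function(ds, bin_boundary = 5) {
  has_sc <- !is.na(ds$compounds$superclass)
  if (!all(has_sc)) {
    warning(sprintf("%d compound(s) without superclass excluded", sum(!has_sc)))
    ds <- select_subset(ds, "classified")
  }
  if (n_compounds(ds) == 0) stop_bitter("validation_error", "no labeled compounds")
  prom <- compound_promiscuity(ds)
  if (any(prom == 0)) {
    stop_bitter("validation_error", "dataset contains compounds activating no receptor")
  }
  bins <- promiscuity_bin(prom, boundary = bin_boundary)
  sc <- ds$compounds$superclass

  rp <- receptor_promiscuity_index(ds)
  rp <- rp[rp > 0]
  rec_order <- names(rp)[order(-rp, names(rp))]
  sc_counts <- table(sc)
  sc_order <- names(sc_counts)[order(-as.integer(sc_counts), names(sc_counts))]
  bin_order <- levels(bins)[levels(bins) %in% as.character(bins)]

  nodes <- rbind(
    data.frame(id = paste0("receptor:", rec_order), layer = "receptor",
               label = rec_order, order = seq_along(rec_order)),
    data.frame(id = paste0("superclass:", sc_order), layer = "superclass",
               label = sc_order, order = seq_along(sc_order)),
    data.frame(id = paste0("bin:", bin_order), layer = "bin",
               label = bin_order, order = seq_along(bin_order))
  )

  links <- list()
  for (r in rec_order) {
    ag <- ds$activation[, r] == 1
    tab <- table(sc[ag])
    tab <- tab[tab > 0]
    for (s in names(tab)) {
      links[[length(links) + 1L]] <- data.frame(
        source = paste0("receptor:", r), target = paste0("superclass:", s),
        value = as.integer(tab[[s]]))
    }
  }
  for (s in sc_order) {
    tab <- table(bins[sc == s])
    tab <- tab[tab > 0]
    for (b in names(tab)) {
      links[[length(links) + 1L]] <- data.frame(
        source = paste0("superclass:", s), target = paste0("bin:", b),
        value = as.integer(tab[[b]]))
    }
  }
  links <- do.call(rbind, links)
  rownames(links) <- NULL
  structure(list(
    nodes = nodes, links = links,
    meta = list(
      bin_boundary = bin_boundary,
      n_compounds = n_compounds(ds),
      n_activations = sum(ds$activation),
      accounting = paste("receptor->superclass edges count (compound, receptor)",
                         "activation pairs; superclass->bin edges count compounds once"))),
    class = "flow_graph")
}

#' @export
print.flow_graph <- function(x, ...) {
  cat(sprintf("<flow_graph> %d nodes, %d links (%d compounds, %d activations)\n",
              nrow(x$nodes), nrow(x$links), x$meta$n_compounds, x$meta$n_activations))
  invisible(x)
}

#' Write / read a flow graph as JSON
#'
#' Structured-text serialization (nodes, links, meta) suitable for alluvial
#' plotting front-ends; the read-back equals the written graph.
#'
#' @param fg a `flow_graph`.
#' @param path output path.
#' @return `path` invisibly for the writer; a `flow_graph` for the reader.
#' @export
write_flows <- function(fg, path) {
  jsonlite::write_json(list(nodes = fg$nodes, links = fg$links, meta = fg$meta),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_flows
#' @export
read_flows <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$meta$bin_boundary <- as.integer(x$meta$bin_boundary)
  x$links$value <- as.integer(x$links$value)
  x$nodes$order <- as.integer(x$nodes$order)
  structure(list(nodes = x$nodes, links = x$links, meta = x$meta),
            class = "flow_graph")
}
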