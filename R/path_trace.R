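#' Walks supporting a predicted link
#'
#' All corpus walks containing both endpoints of the prediction, in
#' deterministic corpus order; when more than \code{max_walks} exist, a
#' seeded uniform subsample of that size is returned (the "five random
#' paths" used for visualization).
#'
#' @param corpus a \code{"walk_corpus"}.
#' @param protein,pathway the two query node ids.
#' @param max_walks maximum number of supporting walks to keep (default 5).
#' @param seed seed for the subsample.
#' @return list of walks (possibly empty).
#' @export
supporting_walks <- function(corpus, protein, pathway, max_walks = 5L,
                             seed = 1L) {
  hit <- vapply(corpus$walks,
                function(w) protein %in% w$nodes && pathway %in% w$nodes,
                TRUE)
  walks <- corpus$walks[hit]
  if (length(walks) > max_walks) {
    set.seed(seed)
    walks <- walks[sort(sample.int(length(walks), max_walks))]
  }
  walks
}

#' Nodes common to supporting walks
#'
#' Counts, for each node, the number of distinct walks it appears in (a
#' node repeated within one walk counts once) and keeps nodes reaching
#' \code{min_support}.  The query endpoints are always included, with their
#' own support counts.
#'
#' @param walks list of walks (e.g. from [supporting_walks()]).
#' @param min_support minimum number of distinct walks (default 5).
#' @param endpoints optional node ids always kept (the query pair).
#' @return data.frame with columns \code{node}, \code{support}, sorted by
#'   decreasing support then id.
#' @export
common_nodes <- function(walks, min_support = 5L, endpoints = character(0)) {
  if (length(walks) == 0L)
    tab <- table(character(0))
  else
    tab <- table(unlist(lapply(walks, function(w) unique(w$nodes))))
  nodes <- names(tab)[tab >= min_support]
  nodes <- union(nodes, endpoints)
  support <- as.integer(tab[nodes])
  support[is.na(support)] <- 0L
  out <- data.frame(node = nodes, support = support,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$node, method = "radix"), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Export an induced subgraph as Cytoscape-compatible tables
#'
#' Writes \code{edges.tsv} (source, target, relation: every graph edge with
#' both endpoints in the node set) and \code{nodes.tsv} (node, type,
#' support) into a directory, in the two-table layout Cytoscape imports.
#'
#' @param graph a \code{"kg"}.
#' @param nodes data.frame with columns \code{node}, \code{support} (as
#'   from [common_nodes()]), or a character vector of node ids.
#' @param dir output directory (created if missing).
#' @return invisibly, list with the induced \code{edges} and \code{nodes}
#'   data.frames.
#' @export
export_subgraph <- function(graph, nodes, dir) {
  if (is.character(nodes))
    nodes <- data.frame(node = nodes, support = NA_integer_,
                        stringsAsFactors = FALSE)
  missing <- setdiff(nodes$node, graph$node_id)
  if (length(missing))
    stop("unknown node(s): ", paste(missing, collapse = ", "))
  e <- graph$edges
  keep <- e$head %in% nodes$node & e$tail %in% nodes$node
  edges <- data.frame(source = e$head[keep], target = e$tail[keep],
                      relation = e$relation[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$relation, edges$target,
                       method = "radix"), , drop = FALSE]
  row.names(edges) <- NULL
  node_tab <- data.frame(node = nodes$node,
                         type = graph$node_type[match(nodes$node,
                                                      graph$node_id)],
                         support = nodes$support, stringsAsFactors = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(node_tab, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(edges = edges, nodes = node_tab))
}

#' Trace the walk support of one prediction
#'
#' Convenience wrapper: supporting walks, common nodes, and (optionally)
#' the exported induced subgraph for a protein--pathway prediction.
#'
#' @inheritParams supporting_walks
#' @param graph a \code{"kg"}.
#' @param min_support see [common_nodes()].
#' @param dir optional output directory for [export_subgraph()].
#' @return list with \code{walks}, \code{nodes}, and (when \code{dir} is
#'   given) the exported tables.
#' @export
trace_prediction <- function(graph, corpus, protein, pathway,
                             min_support = 5L, max_walks = 5L, seed = 1L,
                             dir = NULL) {
  stopifnot(min_support >= 1L, max_walks >= min_support)
  walks <- supporting_walks(corpus, protein, pathway, max_walks, seed)
  nodes <- common_nodes(walks, min_support, endpoints = c(protein, pathway))
  out <- list(walks = walks, nodes = nodes)
  if (!is.null(dir))
    out$subgraph <- export_subgraph(graph, nodes, dir)
  out
}
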