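#' Construct a typed knowledge graph
#'
#' Builds a heterogeneous knowledge graph from a node-type table and a table
#' of subject--predicate--object triples.  Edges are stored directed (as
#' triples) but all traversal operations treat them as undirected; direction
#' is kept only for serialization and for the schema view.  Node types may be
#' organised in a hierarchy (a forest), e.g. \code{DarkKinase} and
#' \code{LightKinase} both having parent \code{Protein}: pattern tokens
#' written against an ancestor label then admit all of its descendants.
#'
#' @param nodes data.frame with columns \code{node} and \code{type}, or a
#'   named character vector mapping node id to type label.
#' @param edges data.frame with columns \code{head}, \code{relation},
#'   \code{tail}.  Parallel edges are allowed and each counts towards degree;
#'   self-loops are rejected.
#' @param hierarchy optional data.frame with columns \code{child},
#'   \code{parent} (type labels), or a named character vector child -> parent.
#' @return An object of class \code{"kg"} with precomputed degree and
#'   per-node neighbor indices.
#' @examples
#' g <- kg(nodes = c(p1 = "Protein", w1 = "Pathway"),
#'         edges = data.frame(head = "p1", relation = "hasPathway",
#'                            tail = "w1"))
#' kg_degree(g, "p1")
#' @export
kg <- function(nodes, edges = NULL, hierarchy = NULL) {
  if (is.data.frame(nodes)) {
    stopifnot(all(c("node", "type") %in% names(nodes)))
    node_map <- stats::setNames(as.character(nodes$type), as.character(nodes$node))
  } else {
    node_map <- nodes
  }
  if (is.null(names(node_map)) || any(names(node_map) == ""))
    stop("nodes must be named (node id -> type label)")
  if (anyDuplicated(names(node_map)))
    stop("duplicate node ids: ",
         paste(unique(names(node_map)[duplicated(names(node_map))]), collapse = ", "))
  ord <- order(names(node_map), method = "radix")
  node_id <- names(node_map)[ord]
  node_type <- unname(node_map[ord])

  hier <- normalize_hierarchy(hierarchy)
  check_hierarchy_forest(hier)

  if (is.null(edges)) {
    edges <- data.frame(head = character(), relation = character(),
                        tail = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("head", "relation", "tail") %in% names(edges)))
  edges <- data.frame(head = as.character(edges$head),
                      relation = as.character(edges$relation),
                      tail = as.character(edges$tail),
                      stringsAsFactors = FALSE)
  hidx <- match(edges$head, node_id)
  tidx <- match(edges$tail, node_id)
  if (anyNA(hidx) || anyNA(tidx)) {
    bad <- unique(c(edges$head[is.na(hidx)], edges$tail[is.na(tidx)]))
    stop("edge endpoint not declared in node table: ",
         paste(bad, collapse = ", "))
  }
  if (any(hidx == tidx))
    stop("self-loop triples are not allowed (node ",
         edges$head[which(hidx == tidx)[1L]], ")")

  g <- structure(list(node_id = node_id, node_type = node_type,
                      edges = edges, hierarchy = hier),
                 class = "kg")
  build_kg_index(g)
}

normalize_hierarchy <- function(hierarchy) {
  if (is.null(hierarchy))
    return(stats::setNames(character(0), character(0)))
  if (is.data.frame(hierarchy)) {
    stopifnot(all(c("child", "parent") %in% names(hierarchy)))
    hierarchy <- stats::setNames(as.character(hierarchy$parent),
                                 as.character(hierarchy$child))
  }
  if (anyDuplicated(names(hierarchy)))
    stop("type hierarchy is not a forest: duplicate child entries")
  hierarchy
}

check_hierarchy_forest <- function(hier) {
  for (lab in names(hier)) {
    seen <- character(0)
    cur <- lab
    while (cur %in% names(hier)) {
      if (cur %in% seen) stop("type hierarchy contains a cycle at '", lab, "'")
      seen <- c(seen, cur)
      cur <- unname(hier[[cur]])
    }
  }
  invisible(TRUE)
}

# incidence index: for node i, adj_rel[[i]] / adj_nbr[[i]] are parallel
# vectors sorted by (relation, neighbor id); one entry per incident edge.
build_kg_index <- function(g) {
  n <- length(g$node_id)
  hidx <- match(g$edges$head, g$node_id)
  tidx <- match(g$edges$tail, g$node_id)
  inc_node <- c(hidx, tidx)
  inc_rel <- c(g$edges$relation, g$edges$relation)
  inc_nbr <- c(tidx, hidx)
  o <- order(inc_node, inc_rel, g$node_id[inc_nbr], method = "radix")
  inc_node <- inc_node[o]; inc_rel <- inc_rel[o]; inc_nbr <- inc_nbr[o]
  f <- factor(inc_node, levels = seq_len(n))
  g$adj_rel <- split(inc_rel, f)
  g$adj_nbr <- split(inc_nbr, f)
  g$degree <- as.integer(lengths(g$adj_rel))
  names(g$degree) <- g$node_id
  g
}

kg_node_index <- function(graph, node) {
  i <- match(node, graph$node_id)
  if (is.na(i)) stop("unknown node: '", node, "'")
  i
}

#' Load a knowledge graph from delimited text files
#'
#' @param triples_path tab-separated file with three columns
#'   \code{head<TAB>relation<TAB>tail}, no header; lines starting with
#'   \code{#} are ignored.
#' @param node_types_path tab-separated file \code{node_id<TAB>type_label}.
#' @param hierarchy_path optional tab-separated file
#'   \code{child_type<TAB>parent_type}.
#' @return A \code{"kg"} object.
#' @export
load_kg <- function(triples_path, node_types_path, hierarchy_path = NULL) {
  types <- read_tsv_columns(node_types_path, 2L)
  hier <- NULL
  if (!is.null(hierarchy_path)) {
    h <- read_tsv_columns(hierarchy_path, 2L)
    hier <- stats::setNames(h[[2L]], h[[1L]])
  }
  tr <- read_tsv_columns(triples_path, 3L)
  kg(nodes = stats::setNames(types[[2L]], types[[1L]]),
     edges = data.frame(head = tr[[1L]], relation = tr[[2L]], tail = tr[[3L]],
                        stringsAsFactors = FALSE),
     hierarchy = hier)
}

# strict reader used for the no-header graph files: reports the 1-based line
# number of any row with the wrong number of fields.
read_tsv_columns <- function(path, ncol) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != ncol)) {
    lineno <- which(keep)[which(nf != ncol)[1L]]
    stop("malformed row at line ", lineno, " of '", path, "': expected ",
         ncol, " tab-separated fields, found ", nf[nf != ncol][1L])
  }
  out <- lapply(seq_len(ncol), function(j) vapply(rows, `[[`, "", j))
  as.data.frame(out, col.names = paste0("V", seq_len(ncol)),
                stringsAsFactors = FALSE)
}

#' Write a knowledge graph to delimited text files
#'
#' Inverse of [load_kg()]: nodes and triples are written sorted so that a
#' write/load round trip reproduces the identical graph.
#'
#' @param graph a \code{"kg"} object.
#' @inheritParams load_kg
#' @export
write_kg <- function(graph, triples_path, node_types_path,
                     hierarchy_path = NULL) {
  stopifnot(inherits(graph, "kg"))
  writeLines(paste(graph$node_id, graph$node_type, sep = "\t"),
             node_types_path)
  e <- graph$edges
  o <- order(e$head, e$relation, e$tail, method = "radix")
  writeLines(paste(e$head[o], e$relation[o], e$tail[o], sep = "\t"),
             triples_path)
  if (!is.null(hierarchy_path)) {
    h <- graph$hierarchy
    writeLines(paste(names(h), unname(h), sep = "\t"), hierarchy_path)
  }
  invisible(graph)
}

#' Enumerate the incident edges of a node
#'
#' Every incident edge is reported as a (relation, neighbor) pair regardless
#' of its stored direction; parallel edges appear once per edge.  Order is
#' deterministic: sorted by relation label, then neighbor id.
#'
#' @param graph a \code{"kg"} object.
#' @param node a node id.
#' @param relation optional edge-type label; when given, only that
#'   relation's incident edges are returned.
#' @return data.frame with columns \code{relation}, \code{neighbor}.
#' @export
kg_neighbors <- function(graph, node, relation = NULL) {
  i <- kg_node_index(graph, node)
  rel <- graph$adj_rel[[i]]
  nbr <- graph$node_id[graph$adj_nbr[[i]]]
  if (!is.null(relation)) {
    keep <- rel == relation
    rel <- rel[keep]; nbr <- nbr[keep]
  }
  data.frame(relation = rel, neighbor = nbr, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Degree of a node
#'
#' Counts incident edges, not distinct neighbors: parallel edges under
#' different (or equal) relations each contribute 1.  This is the same
#' convention the walk bias uses, so that the per-relation edge proportions
#' g(r) sum to one over a node's edges.
#'
#' @inheritParams kg_neighbors
#' @return integer count.
#' @export
kg_degree <- function(graph, node) {
  i <- kg_node_index(graph, node)
  graph$degree[[i]]
}

#' Per-relation edge proportions of a node
#'
#' For node v, \code{g(r)} is the fraction of v's incident edges that carry
#' relation r.  The values sum to 1.  Undefined (an error) for isolated
#' nodes.
#'
#' @inheritParams kg_neighbors
#' @return named numeric vector, one entry per relation incident to the
#'   node, sorted by relation label.
#' @export
relation_profile <- function(graph, node) {
  i <- kg_node_index(graph, node)
  rel <- graph$adj_rel[[i]]
  if (length(rel) == 0L)
    stop("relation profile undefined for degree-0 node '", node, "'")
  tab <- table(rel)
  stats::setNames(as.numeric(tab) / length(rel), names(tab))
}

#' Schema (meta-graph) of a knowledge graph
#'
#' Projects every instance edge through the node-type mapping, yielding the
#' distinct (source type, relation, target type) triples.  Subtype labels
#' are reported as-is (a DarkKinase--Pathway edge is not collapsed to
#' Protein--Pathway).  A protein-protein interaction appears as a loop edge
#' at the Protein type.
#'
#' @param graph a \code{"kg"} object.
#' @return object of class \code{"kg_schema"}: data.frame with columns
#'   \code{source_type}, \code{relation}, \code{target_type}, sorted,
#'   no duplicates.
#' @export
schema_view <- function(graph) {
  st <- graph$node_type[match(graph$edges$head, graph$node_id)]
  tt <- graph$node_type[match(graph$edges$tail, graph$node_id)]
  s <- unique(data.frame(source_type = st, relation = graph$edges$relation,
                         target_type = tt, stringsAsFactors = FALSE))
  s <- s[order(s$source_type, s$relation, s$target_type, method = "radix"), ,
         drop = FALSE]
  row.names(s) <- NULL
  class(s) <- c("kg_schema", "data.frame")
  s
}

#' Summary statistics of a knowledge graph
#'
#' @param graph a \code{"kg"} object.
#' @return list with \code{node_counts} (per type), \code{edge_counts}
#'   (per relation) and \code{mean_degree} (per type).
#' @export
kg_stats <- function(graph) {
  node_counts <- table(graph$node_type)
  mean_degree <- tapply(graph$degree, graph$node_type, mean)
  list(n_nodes = length(graph$node_id), n_edges = nrow(graph$edges),
       node_counts = node_counts,
       edge_counts = if (nrow(graph$edges)) table(graph$edges$relation)
                     else table(character(0)),
       mean_degree = mean_degree)
}

#' All declared type labels of a graph
#'
#' The union of the labels used by nodes and the labels appearing in the
#' type hierarchy (a parent such as \code{Protein} is part of the alphabet
#' even if no node carries it directly).
#'
#' @param graph a \code{"kg"} object.
#' @return character vector, sorted.
#' @export
type_alphabet <- function(graph) {
  sort(unique(c(graph$node_type, names(graph$hierarchy),
                unname(graph$hierarchy))))
}

#' Ancestor chain of a type label (self first)
#' @param graph a \code{"kg"} object (or a named child -> parent vector).
#' @param label a type label.
#' @return character vector: label, parent, grandparent, ...
#' @export
type_ancestors <- function(graph, label) {
  hier <- if (inherits(graph, "kg")) graph$hierarchy else graph
  out <- label
  while (label %in% names(hier)) {
    label <- unname(hier[[label]])
    out <- c(out, label)
  }
  out
}

# all labels whose ancestor chain contains `label` (including itself)
type_descendants <- function(hier, label, alphabet) {
  alphabet[vapply(alphabet,
                  function(a) label %in% type_ancestors(hier, a), TRUE)]
}

#' @export
print.kg <- function(x, ...) {
  s <- kg_stats(x)
  cat("Heterogeneous knowledge graph\n")
  cat("  nodes:", s$n_nodes, "of", length(unique(x$node_type)), "types\n")
  cat("  edges:", s$n_edges, "of", length(unique(x$edges$relation)),
      "relation types\n")
  if (length(x$hierarchy))
    cat("  type hierarchy:",
        paste(names(x$hierarchy), "<", unname(x$hierarchy), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
print.kg_schema <- function(x, ...) {
  cat("Schema view (", nrow(x), " typed edges)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
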