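#' Curation filters for raw association tables
#'
#' Source-specific rules that reduce raw association exports to the rows
#' worth loading into the knowledge graph.  All numeric thresholds are
#' strict inequalities (scores must exceed the threshold to survive), and
#' every filter is a pure row predicate: idempotent and independent of row
#' order.
#'
#' @name curation
NULL

require_column <- function(table, col) {
  if (!col %in% names(table))
    stop("association table lacks required column '", col, "'")
  invisible(TRUE)
}

#' Keep only associations with an allowed evidence code
#'
#' Pathway-membership exports carry evidence codes; only manually curated
#' rows (code TAS, traceable author statement) are kept by default, while
#' electronically inferred rows (IEA) are dropped.
#'
#' @param table data.frame with an \code{evidence} column.
#' @param allowed evidence codes to keep (default \code{"TAS"}).
#' @return the filtered data.frame (row order preserved).
#' @export
filter_reactome_evidence <- function(table, allowed = "TAS") {
  require_column(table, "evidence")
  out <- table[table$evidence %in% allowed, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Prune pathway rows under excluded hierarchy roots
#'
#' Removes rows whose pathway lies in the descendant closure of any exclude
#' root, unless the pathway is also under (or is) a keep root; keep
#' overrides exclude.  The shipped defaults encode the one documented
#' example: everything beneath \code{Disease} (R-HSA-1643685) is too general
#' and is dropped, except the \code{Infectious disease} (R-HSA-5663205)
#' subtree.
#'
#' @param table data.frame with a \code{pathway} column.
#' @param hierarchy data.frame with columns \code{child}, \code{parent}.
#' @param exclude_roots,keep_roots pathway ids; roots absent from the
#'   hierarchy are no-ops.
#' @param pathway_col name of the pathway column.
#' @return the filtered data.frame.
#' @export
prune_pathway_hierarchy <- function(table, hierarchy,
                                    exclude_roots = "R-HSA-1643685",
                                    keep_roots = "R-HSA-5663205",
                                    pathway_col = "pathway") {
  require_column(table, pathway_col)
  stopifnot(all(c("child", "parent") %in% names(hierarchy)))
  excl <- descendant_closure(hierarchy, exclude_roots)
  keep <- descendant_closure(hierarchy, keep_roots)
  drop <- table[[pathway_col]] %in% setdiff(excl, keep)
  out <- table[!drop, , drop = FALSE]
  row.names(out) <- NULL
  out
}

# all ids reachable downward from the roots, roots included; errors on a
# cyclic hierarchy
descendant_closure <- function(hierarchy, roots) {
  child <- as.character(hierarchy$child)
  parent <- as.character(hierarchy$parent)
  # acyclicity check: repeatedly peel ids with no remaining parent link
  ids <- unique(c(child, parent))
  live <- rep(TRUE, length(child))
  repeat {
    has_child <- ids %in% parent[live]
    is_child <- ids %in% child[live]
    leaves <- ids[is_child & !has_child]
    if (length(leaves) == 0L) break
    live <- live & !(child %in% leaves)
    ids <- setdiff(ids, leaves)
  }
  if (any(ids %in% child[live]))
    stop("pathway hierarchy contains a cycle")
  children <- split(child, parent)
  seen <- character(0)
  frontier <- as.character(roots)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(children[frontier])), seen)
  }
  seen
}

#' Drop over-general annotation terms
#'
#' A term annotated to more than \code{max_associations} rows is considered
#' too general to be informative and is removed entirely (all of its rows).
#' The default cap of 5000 matches the curation rule for gene-ontology
#' annotations.
#'
#' @param table data.frame with a term column.
#' @param max_associations strict cap: terms with row count >
#'   \code{max_associations} are removed.
#' @param term_col name of the term column (default \code{"go_term"}).
#' @return the filtered data.frame.
#' @export
filter_go_generality <- function(table, max_associations = 5000L,
                                 term_col = "go_term") {
  require_column(table, term_col)
  cnt <- table(table[[term_col]])
  general <- names(cnt)[cnt > max_associations]
  out <- table[!(table[[term_col]] %in% general), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Filter protein-protein interactions by experimental score and kinase
#' involvement
#'
#' Keeps a row iff its experimental evidence score strictly exceeds the
#' threshold (default 700) and at least one endpoint is a kinase.
#'
#' @param table data.frame with endpoint columns and an
#'   \code{experimental_score} column.
#' @param min_experimental_score strict threshold (default 700).
#' @param kinase_ids node ids counted as kinases.
#' @param endpoint_cols the two endpoint columns.
#' @return the filtered data.frame.
#' @export
filter_string_ppi <- function(table, min_experimental_score = 700,
                              kinase_ids,
                              endpoint_cols = c("protein1", "protein2")) {
  require_column(table, "experimental_score")
  for (col in endpoint_cols) require_column(table, col)
  score_ok <- as.numeric(table$experimental_score) > min_experimental_score
  kin_ok <- table[[endpoint_cols[[1L]]]] %in% kinase_ids |
            table[[endpoint_cols[[2L]]]] %in% kinase_ids
  out <- table[score_ok & kin_ok, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Filter post-translational-modification rows by confidence
#'
#' @param table data.frame with a \code{confidence} column.
#' @param min_confidence strict threshold (default 1.0).
#' @return the filtered data.frame.
#' @export
filter_ptm_confidence <- function(table, min_confidence = 1.0) {
  require_column(table, "confidence")
  out <- table[as.numeric(table$confidence) > min_confidence, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Remove rows annotating excluded protein domains
#'
#' Kinase catalytic domains (\code{Pkinase}, \code{Pkinase_Tyr}) are carried
#' by essentially every kinase and are removed by default: they would
#' connect all kinases through a single hub.
#'
#' @param table data.frame with a domain column.
#' @param excluded_domains domain names to drop.
#' @param domain_col name of the domain column.
#' @return the filtered data.frame.
#' @export
filter_pfam_domains <- function(table,
                                excluded_domains = c("Pkinase",
                                                     "Pkinase_Tyr"),
                                domain_col = "domain") {
  require_column(table, domain_col)
  out <- table[!(table[[domain_col]] %in% excluded_domains), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Read / write an association table (TSV with header)
#' @param path file path.
#' @param source optional provenance tag stored as the \code{"source"}
#'   attribute.
#' @export
read_association_table <- function(path, source = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(source)) attr(tab, "source") <- source
  tab
}

#' @rdname read_association_table
#' @param table a data.frame.
#' @export
write_association_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}
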