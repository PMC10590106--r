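#' Walk configuration
#'
#' @param walk_length maximum number of nodes collected per walk (L).  The
#'   shipped default of 5 follows the illustrative walk length of the
#'   method's schematic; it is a tunable, not a calibrated value.
#' @param num_walks walks started per eligible node (NW); 40 is the value
#'   the robustness sweep identifies as optimal.
#' @param seed master seed; every walk derives its own stream from it.
#' @param start_types type labels eligible to start a walk (resolved through
#'   the type hierarchy), or NULL for every node admissible at the DFA start.
#' @param bias \code{"two-stage"} (default: relation chosen in proportion to
#'   its edge share g(r), then neighbor by normalized inverse degree within
#'   the relation), \code{"single-stage"} (probability proportional to
#'   g(r)/degree(neighbor) over all admissible steps jointly), or
#'   \code{"uniform"} (uniform over admissible steps; used as the no-bias
#'   control).
#' @return list of class \code{"walk_config"}.
#' @export
walk_config <- function(walk_length = 5L, num_walks = 40L, seed = 1L,
                        start_types = NULL,
                        bias = c("two-stage", "single-stage", "uniform")) {
  bias <- match.arg(bias)
  stopifnot(walk_length >= 2L, num_walks >= 1L)
  structure(list(walk_length = as.integer(walk_length),
                 num_walks = as.integer(num_walks),
                 seed = as.integer(seed),
                 start_types = start_types, bias = bias),
            class = "walk_config")
}

# Precomputed integer-indexed view of (graph, dfa) used by the samplers:
# per node, parallel vectors of relation id, neighbor index, neighbor
# inverse degree and neighbor symbol column in the DFA alphabet.
walk_context <- function(graph, dfa) {
  sym <- match(graph$node_type, dfa$alphabet)
  relations <- sort(unique(graph$edges$relation))
  adj_relid <- lapply(graph$adj_rel, match, table = relations)
  adj_nbr <- graph$adj_nbr
  invdeg <- 1 / pmax(graph$degree, 1L)
  list(graph = graph, dfa = dfa, sym = sym, relations = relations,
       adj_relid = adj_relid, adj_nbr = adj_nbr, invdeg = invdeg,
       degree = graph$degree)
}

# probabilities over incidence entries of node i whose neighbor symbol is
# in `allowed_states` terms: admissible = entries for which
# trans[state, sym(nbr)] is in `targets` (any nonzero when targets=NULL)
step_probs <- function(ctx, i, state, bias, targets = NULL) {
  relid <- ctx$adj_relid[[i]]
  nbrs <- ctx$adj_nbr[[i]]
  if (length(nbrs) == 0L) return(NULL)
  nsym <- ctx$sym[nbrs]
  tr <- ctx$dfa$trans[state, ]
  dest <- ifelse(is.na(nsym), 0L, tr[nsym])
  adm <- if (is.null(targets)) dest != 0L else dest %in% targets
  if (!any(adm)) return(NULL)
  p <- numeric(length(nbrs))
  if (bias == "uniform") {
    p[adm] <- 1 / sum(adm)
  } else if (bias == "single-stage") {
    cnt <- tabulate(relid, nbins = length(ctx$relations))
    g <- cnt[relid] / length(relid)
    w <- g[adm] * ctx$invdeg[nbrs[adm]]
    p[adm] <- w / sum(w)
  } else { # two-stage
    cnt <- tabulate(relid, nbins = length(ctx$relations))
    adm_rels <- unique(relid[adm])
    grel <- cnt[adm_rels] / length(relid)
    grel <- grel / sum(grel)
    for (k in seq_along(adm_rels)) {
      sel <- adm & relid == adm_rels[[k]]
      w <- ctx$invdeg[nbrs[sel]]
      p[sel] <- grel[[k]] * w / sum(w)
    }
  }
  list(idx = which(adm), p = p[adm], dest = dest)
}

#' Transition probabilities of one walk step
#'
#' Computes the probability of each admissible (relation, neighbor) step
#' from a node given the DFA state, under the inverse-degree walk bias.  A
#' neighbor is admissible iff the DFA has a transition from \code{state} on
#' the neighbor's type label; disallowed steps carry probability zero and
#' are excluded from normalization, as are relations with no admissible
#' neighbor.  Probabilities sum to 1; an empty result signals a stuck walk.
#'
#' @param graph a \code{"kg"} object.
#' @param dfa a \code{"walk_dfa"}.
#' @param state current DFA state.
#' @param node current node id.
#' @param bias see [walk_config()].
#' @return data.frame with columns \code{relation}, \code{neighbor},
#'   \code{probability} (parallel edges aggregated), sorted by relation then
#'   neighbor; zero rows when no step is admissible.
#' @export
transition_distribution <- function(graph, dfa, state, node,
                                    bias = c("two-stage", "single-stage",
                                             "uniform")) {
  bias <- match.arg(bias)
  ctx <- walk_context(graph, dfa)
  i <- kg_node_index(graph, node)
  if (!is.numeric(state) || state < 1L || state > dfa$n_states)
    stop("invalid DFA state: ", state)
  sp <- step_probs(ctx, i, state, bias)
  empty <- data.frame(relation = character(), neighbor = character(),
                      probability = numeric(), stringsAsFactors = FALSE)
  if (is.null(sp)) return(empty)
  rel <- ctx$relations[ctx$adj_relid[[i]][sp$idx]]
  nbr <- graph$node_id[ctx$adj_nbr[[i]][sp$idx]]
  agg <- stats::aggregate(list(probability = sp$p),
                          by = list(relation = rel, neighbor = nbr), FUN = sum)
  agg <- agg[order(agg$relation, agg$neighbor, method = "radix"), ,
             drop = FALSE]
  row.names(agg) <- NULL
  agg
}

# one walk from start index; uses the current RNG stream
generate_walk_impl <- function(ctx, start, L, bias) {
  dfa <- ctx$dfa
  nodes <- start
  phases <- "forward"
  s0 <- dfa$start
  ssym <- ctx$sym[[start]]
  s1 <- if (is.na(ssym)) 0L else dfa$trans[[s0, ssym]]
  if (s1 == DFA_REJECT)
    stop("start node '", ctx$graph$node_id[[start]],
         "' is not admissible at the pattern start")
  states <- c(s0, s1)
  cur <- start
  accepted <- dfa$accepting[[s1]]
  p <- 1L # consumed symbols

  while (!accepted && length(nodes) < L) {
    sp <- step_probs(ctx, cur, states[[p + 1L]], bias)
    if (is.null(sp)) break # stuck forward: truncated walk is kept
    pick <- sp$idx[[sample.int(length(sp$p), 1L, prob = sp$p)]]
    cur <- ctx$adj_nbr[[cur]][[pick]]
    nodes <- c(nodes, cur)
    phases <- c(phases, "forward")
    p <- p + 1L
    states <- c(states, ctx$dfa$trans[[states[[p]], ctx$sym[[cur]]]])
    accepted <- dfa$accepting[[states[[p + 1L]]]]
  }

  if (accepted && length(nodes) < L) {
    # terminal node is collected again, then the walk runs the pattern in
    # reverse: each backward step re-enters the previous pattern position,
    # choosing any neighbor whose label reproduces the recorded state path
    nodes <- c(nodes, cur)
    phases <- c(phases, "reverse")
    while (length(nodes) < L && p >= 2L) {
      targets <- states[[p]] # state to land in, entered from states[[p-1]]
      sp <- step_probs(ctx, cur, states[[p - 1L]], bias, targets = targets)
      if (is.null(sp)) break
      pick <- sp$idx[[sample.int(length(sp$p), 1L, prob = sp$p)]]
      cur <- ctx$adj_nbr[[cur]][[pick]]
      nodes <- c(nodes, cur)
      phases <- c(phases, "reverse")
      p <- p - 1L
    }
  }

  list(nodes = ctx$graph$node_id[nodes],
       types = ctx$graph$node_type[nodes],
       phase = phases)
}

#' Generate one pattern-constrained walk
#'
#' Samples forward steps from [transition_distribution()] until the pattern
#' accepts, the walk-length budget is reached, or no admissible neighbor
#' remains (the truncated walk is kept).  On acceptance with budget
#' remaining, the terminal node is emitted a second time and the walk
#' continues in reverse through the pattern positions, popping the DFA state
#' stack; a single reverse pass is performed.  Uses the current RNG stream;
#' seed with \code{set.seed()} for reproducibility.
#'
#' @param graph a \code{"kg"}.
#' @param dfa a \code{"walk_dfa"}.
#' @param start starting node id; must be admissible at the DFA start.
#' @param config a [walk_config()].
#' @return list with \code{nodes}, \code{types} and \code{phase}
#'   (\code{"forward"}/\code{"reverse"}) character vectors.
#' @export
generate_walk <- function(graph, dfa, start, config = walk_config()) {
  ctx <- walk_context(graph, dfa)
  i <- kg_node_index(graph, start)
  if (!is.null(config$start_types) &&
      !any(type_ancestors(graph, graph$node_type[[i]]) %in%
           config$start_types))
    stop("start node '", start, "' has type '", graph$node_type[[i]],
         "', not one of the eligible start types")
  generate_walk_impl(ctx, i, config$walk_length, config$bias)
}

# per-(start, repetition) derived seed; documented counter scheme so that
# corpora are reproducible and independent of generation order
derive_seed <- function(master, i, j) {
  as.integer(((master %% 32768) * 48271 + i * 97003 + j * 7919) %% 2147483647)
}

#' Generate a walk corpus
#'
#' Starts \code{num_walks} walks from every eligible node (sorted id
#' order).  Eligible means: the node's type is admissible at the DFA start
#' and, when \code{start_types} is set, resolves through the hierarchy to
#' one of them.  Each (start, repetition) pair runs on its own seed derived
#' from the master seed, so the corpus is byte-reproducible.
#'
#' @inheritParams generate_walk
#' @return object of class \code{"walk_corpus"}: list of walks plus
#'   generation metadata.
#' @export
generate_corpus <- function(graph, dfa, config = walk_config()) {
  ctx <- walk_context(graph, dfa)
  adm0 <- !is.na(ctx$sym) & ctx$dfa$trans[ctx$dfa$start, ][
    ifelse(is.na(ctx$sym), 1L, ctx$sym)] != 0L
  eligible <- which(adm0)
  if (!is.null(config$start_types)) {
    ok <- vapply(eligible, function(i)
      any(type_ancestors(graph, graph$node_type[[i]]) %in%
          config$start_types), TRUE)
    eligible <- eligible[ok]
  }
  if (length(eligible) == 0L)
    stop("no eligible start nodes for this pattern/start-type configuration")
  walks <- vector("list", length(eligible) * config$num_walks)
  k <- 0L
  for (ii in seq_along(eligible)) {
    for (j in seq_len(config$num_walks)) {
      k <- k + 1L
      set.seed(derive_seed(config$seed, ii, j))
      walks[[k]] <- generate_walk_impl(ctx, eligible[[ii]],
                                       config$walk_length, config$bias)
    }
  }
  structure(list(walks = walks, seed = config$seed, config = config,
                 pattern_text = dfa$pattern_text,
                 graph_fingerprint = kg_fingerprint(graph)),
            class = "walk_corpus")
}

kg_fingerprint <- function(graph) {
  e <- graph$edges
  paste0("n", length(graph$node_id), "e", nrow(e), "h",
         sum(utf8ToInt(paste(graph$node_id, collapse = ""))) %% 1e9, "x",
         if (nrow(e)) sum(nchar(e$head) + nchar(e$relation) + nchar(e$tail))
         else 0L)
}

#' Write / read a walk corpus
#'
#' One walk per line, node ids space-separated (the skip-gram training
#' format), plus a JSON metadata sidecar (\code{<path>.meta.json}) holding
#' the seed, configuration, pattern text and graph fingerprint.  Reading
#' restores node sequences (and types when a graph is supplied); per-node
#' phase marks are in-memory provenance and are not serialized.
#'
#' @param corpus a \code{"walk_corpus"}.
#' @param path output file path.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "walk_corpus"))
  writeLines(vapply(corpus$walks, function(w) paste(w$nodes, collapse = " "),
                    ""), path)
  meta <- list(seed = corpus$seed,
               walk_length = corpus$config$walk_length,
               num_walks = corpus$config$num_walks,
               bias = corpus$config$bias,
               pattern = corpus$pattern_text,
               graph_fingerprint = corpus$graph_fingerprint)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(corpus)
}

#' @rdname write_corpus
#' @param graph optional \code{"kg"} used to restore type labels.
#' @export
read_corpus <- function(path, graph = NULL) {
  lines <- readLines(path, warn = FALSE)
  walks <- lapply(lines, function(l) {
    ids <- strsplit(l, " ", fixed = TRUE)[[1L]]
    w <- list(nodes = ids)
    if (!is.null(graph))
      w$types <- graph$node_type[match(ids, graph$node_id)]
    w
  })
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  structure(list(walks = walks, seed = meta$seed, config = meta,
                 pattern_text = meta$pattern,
                 graph_fingerprint = meta$graph_fingerprint),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat("Walk corpus:", length(x$walks), "walks\n")
  if (!is.null(x$pattern_text)) cat("  pattern:", x$pattern_text, "\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}
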