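# shared in-code fixtures; everything is generated, nothing is stored

star_kg <- function() {
  # hub h with three leaves; leaf degrees controlled via extra pendant
  # nodes: n1 deg 1, n2 deg 2, n4 deg 4 (counting their pendant edges)
  kg(nodes = c(h = "A", n1 = "B", n2 = "B", n4 = "B",
               x1 = "C", x2 = "C", x3 = "C", x4 = "C"),
     edges = data.frame(
       head = c("h", "h", "h", "n2", "n4", "n4", "n4"),
       relation = "r",
       tail = c("n1", "n2", "n4", "x1", "x2", "x3", "x4")))
}

chain_kg <- function() {
  # p1 - g1 - p2 - w1, unique admissible choice at every step
  kg(nodes = c(p1 = "Protein", g1 = "GOTerm", p2 = "Protein",
               w1 = "Pathway"),
     edges = data.frame(head = c("p1", "g1", "p2"),
                        relation = c("hasGO", "hasGO", "hasPathway"),
                        tail = c("g1", "p2", "w1")))
}

relation_star_kg <- function() {
  # center c: relation a has 3 edges, b has 1; one unit-degree admissible
  # neighbor per relation plus extra a-edges to inadmissible nodes
  kg(nodes = c(c = "A", u = "B", v = "B", z1 = "D", z2 = "D"),
     edges = data.frame(head = c("c", "c", "c", "c"),
                        relation = c("a", "a", "a", "b"),
                        tail = c("u", "z1", "z2", "v")))
}

random_kg <- function(seed, n_nodes = 60L, n_edges = 150L,
                      types = c("A", "B", "C", "D"),
                      rels = c("r1", "r2", "r3")) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n_nodes))
  nodes <- stats::setNames(sample(types, n_nodes, replace = TRUE), ids)
  h <- sample(ids, n_edges, replace = TRUE)
  t <- sample(ids, n_edges, replace = TRUE)
  keep <- h != t
  kg(nodes = nodes,
     edges = data.frame(head = h[keep],
                        relation = sample(rels, sum(keep), replace = TRUE),
                        tail = t[keep]))
}

small_sim_config <- function(seed = 17L)
  synthetic_kg_config(proteins_per_pathway = 10L, seed = seed)

dark_pairs <- function(truth)
  with(truth[truth$dark, ], data.frame(head = protein, tail = pathway,
                                       stringsAsFactors = FALSE))

# checks that a walk is consistent with the DFA and the graph: forward
# labels form a valid prefix, phases are forward* reverse*, the reverse
# block starts by re-emitting the terminal node and then retraces the
# recorded state path backwards along graph edges
validate_walk <- function(graph, dfa, walk) {
  n <- length(walk$nodes)
  fwd <- walk$phase == "forward"
  if (any(diff(fwd) > 0)) return("reverse before forward")
  m <- sum(fwd)
  stack <- tryCatch(dfa_state_stack(dfa, walk$types[seq_len(m)]),
                    error = function(e) NULL)
  if (is.null(stack)) return("forward labels not a valid DFA prefix")
  for (i in seq_len(m - 1L)) {
    nb <- kg_neighbors(graph, walk$nodes[[i]])$neighbor
    if (!(walk$nodes[[i + 1L]] %in% nb)) return("forward step not an edge")
  }
  if (m < n) {
    if (!dfa$accepting[[stack[[m + 1L]]]])
      return("reverse without acceptance")
    if (walk$nodes[[m + 1L]] != walk$nodes[[m]])
      return("missing terminal re-emission")
    p <- m
    i <- m + 1L
    while (i < n) {
      i <- i + 1L
      if (p < 2L) return("reversed past the pattern start")
      allowed <- dfa$alphabet[dfa$trans[stack[[p - 1L]], ] == stack[[p]]]
      if (!(walk$types[[i]] %in% allowed))
        return("reverse label breaks the state path")
      nb <- kg_neighbors(graph, walk$nodes[[i - 1L]])$neighbor
      if (!(walk$nodes[[i]] %in% nb)) return("reverse step not an edge")
      p <- p - 1L
    }
  }
  TRUE
}
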