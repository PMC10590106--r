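# independent reference implementations used as test oracles; these never
# call the code paths they check

# recursive-descent matcher for a parsed pattern over plain label sets
# (no automaton involved)
ref_pattern_match <- function(pattern, labels, hierarchy = character(0)) {
  alphabet <- pattern$alphabet
  expand <- function(labs) {
    anc <- function(l) {
      out <- l
      while (l %in% names(hierarchy)) { l <- hierarchy[[l]]; out <- c(out, l) }
      out
    }
    alphabet[vapply(alphabet, function(a) any(anc(a) %in% labs), TRUE)]
  }
  sets <- lapply(pattern$tokens, function(tok) {
    if (tok$kind == "negated") setdiff(alphabet, expand(tok$labels))
    else expand(tok$labels)
  })
  quants <- vapply(pattern$tokens, `[[`, "", "quantifier")
  n <- length(labels)
  rec <- function(i, pos) {
    if (i > length(sets)) return(pos == n + 1L)
    s <- sets[[i]]; q <- quants[[i]]
    if (q %in% c("optional", "star") && rec(i + 1L, pos)) return(TRUE)
    if (pos > n || !(labels[[pos]] %in% s)) return(FALSE)
    if (q == "one" || q == "optional") return(rec(i + 1L, pos + 1L))
    # plus / star: consume 1..k matching symbols
    k <- pos
    while (k <= n && labels[[k]] %in% s) {
      if (rec(i + 1L, k + 1L)) return(TRUE)
      k <- k + 1L
    }
    FALSE
  }
  rec(1L, 1L)
}

# all strings (as lists of labels) over `alphabet` of length 0..maxlen
all_strings <- function(alphabet, maxlen) {
  out <- list(character(0))
  for (len in seq_len(maxlen)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, lapply(seq_len(nrow(grid)),
                         function(i) as.character(grid[i, ])))
  }
  out
}

# pairwise-ordering AUC: fraction of positive-negative pairs ordered
# correctly, ties counting one half
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exact rational reconstruction of the two-stage step distribution on a
# node: integer numerators over a common denominator
exact_two_stage <- function(graph, dfa, state, node) {
  nb <- kg_neighbors(graph, node)
  deg <- kg_degree(graph, node)
  lab <- graph$node_type[match(nb$neighbor, graph$node_id)]
  adm <- vapply(lab, function(l) dfa_step(dfa, state, l) != DFA_REJECT, TRUE)
  if (!any(adm)) return(NULL)
  cnt <- table(nb$relation)
  adm_rels <- sort(unique(nb$relation[adm]))
  gnum <- as.numeric(cnt[adm_rels])      # relation weight numerators
  gden <- sum(gnum)
  rows <- list()
  for (r in adm_rels) {
    sel <- adm & nb$relation == r
    degs <- vapply(nb$neighbor[sel], function(v) kg_degree(graph, v), 0L)
    dl <- Reduce(function(a, b) a * b / gcd2(a, b), degs) # lcm
    wnum <- dl / degs
    wden <- sum(wnum)
    for (j in seq_along(wnum))
      rows[[length(rows) + 1L]] <- data.frame(
        relation = r, neighbor = nb$neighbor[sel][[j]],
        num = as.numeric(cnt[[r]]) * wnum[[j]], den = gden * wden,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# induced edge count by brute-force scan of the triple table
induced_edges_oracle <- function(graph, nodes) {
  e <- graph$edges
  sum(e$head %in% nodes & e$tail %in% nodes)
}
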