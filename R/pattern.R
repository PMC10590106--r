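#' Parse a regular pattern over node-type labels
#'
#' A pattern is a whitespace-separated sequence of tokens; each token is a
#' type literal (\code{Protein}), a positive class (\code{[A,B]}) or a
#' negated class (\code{[^Pathway]}), optionally followed by a quantifier
#' \code{+} (one or more), \code{*} (zero or more) or \code{?} (optional).
#' The canonical protein-to-pathway pattern is
#' \code{"Protein [^Pathway]+ Protein Pathway"}: start at a protein, pass
#' through one or more non-pathway nodes, then a protein immediately
#' followed by a pathway.
#'
#' @param text the pattern string.
#' @param alphabet declared type labels (including hierarchy labels that no
#'   node carries directly, e.g. \code{Protein} when nodes are typed
#'   \code{DarkKinase}).
#' @return An object of class \code{"reg_pattern"}: a list of tokens, each
#'   with \code{kind} (\code{literal}, \code{class}, \code{negated}),
#'   \code{labels} and \code{quantifier} (\code{one}, \code{plus},
#'   \code{star}, \code{optional}).
#' @export
parse_pattern <- function(text, alphabet) {
  raw <- strsplit(trimws(text), "\\s+")[[1L]]
  if (length(raw) == 0L || identical(raw, ""))
    stop("syntax error: empty pattern")
  quant_map <- c("+" = "plus", "*" = "star", "?" = "optional")
  tokens <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    tok <- raw[[i]]
    quant <- "one"
    last <- substr(tok, nchar(tok), nchar(tok))
    if (last %in% names(quant_map)) {
      quant <- quant_map[[last]]
      tok <- substr(tok, 1L, nchar(tok) - 1L)
    }
    if (startsWith(tok, "[")) {
      if (!endsWith(tok, "]") || nchar(tok) < 3L)
        stop("syntax error at token ", i, ": malformed class '", raw[[i]], "'")
      body <- substr(tok, 2L, nchar(tok) - 1L)
      kind <- "class"
      if (startsWith(body, "^")) {
        kind <- "negated"
        body <- substr(body, 2L, nchar(body))
      }
      labels <- trimws(strsplit(body, ",", fixed = TRUE)[[1L]])
      if (length(labels) == 0L || any(labels == ""))
        stop("syntax error at token ", i, ": empty class '", raw[[i]], "'")
    } else {
      if (grepl("[][^]", tok) || tok == "")
        stop("syntax error at token ", i, ": '", raw[[i]], "'")
      kind <- "literal"
      labels <- tok
    }
    unknown <- setdiff(labels, alphabet)
    if (length(unknown))
      stop("vocabulary error at token ", i, ": unknown type label ",
           paste0("'", unknown, "'", collapse = ", "))
    tokens[[i]] <- list(kind = kind, labels = labels, quantifier = quant)
  }
  structure(list(tokens = tokens, text = text, alphabet = sort(alphabet)),
            class = "reg_pattern")
}

# concrete symbol set a token admits, after expanding each of its labels to
# the label plus all declared descendants (DarkKinase satisfies Protein)
token_symbols <- function(token, alphabet, hier) {
  expand <- function(labs)
    unique(unlist(lapply(labs, type_descendants, hier = hier,
                         alphabet = alphabet)))
  if (token$kind == "negated") setdiff(alphabet, expand(token$labels))
  else expand(token$labels)
}

#' Compile a regular pattern to a deterministic finite automaton
#'
#' Builds a Thompson-style NFA over the concrete type alphabet (pattern
#' labels are expanded through the type hierarchy, so a \code{DarkKinase}
#' node is admitted wherever \code{Protein} is) and determinises it by
#' subset construction.  The DFA is the walk constraint: an undefined
#' transition means the corresponding step has probability zero.
#'
#' @param pattern a \code{"reg_pattern"} from [parse_pattern()], or a
#'   pattern string.
#' @param alphabet concrete type labels the automaton must decide over.
#' @param hierarchy optional named character vector (child type -> parent
#'   type), or a \code{"kg"} object whose hierarchy is used.
#' @return An object of class \code{"walk_dfa"}: transition matrix
#'   \code{trans[state, symbol]} with 0 meaning reject, \code{start} state 1,
#'   logical \code{accepting}, and the symbol \code{alphabet}.
#' @export
compile_dfa <- function(pattern, alphabet, hierarchy = NULL) {
  hier <- if (inherits(hierarchy, "kg")) hierarchy$hierarchy
          else normalize_hierarchy(hierarchy)
  alphabet <- sort(unique(alphabet))
  if (is.character(pattern))
    pattern <- parse_pattern(pattern, unique(c(alphabet, names(hier),
                                               unname(hier))))
  stopifnot(inherits(pattern, "reg_pattern"))

  # NFA: states 1..(k+1), state i = "about to read token i";
  # edges carry a symbol set; eps[[i]] holds epsilon successors.
  k <- length(pattern$tokens)
  n_nfa <- k + 1L
  edges_from <- integer(0); edges_to <- integer(0); edges_sym <- list()
  eps <- rep(list(integer(0)), n_nfa)
  for (i in seq_len(k)) {
    tok <- pattern$tokens[[i]]
    syms <- token_symbols(tok, alphabet, hier)
    edges_from <- c(edges_from, i); edges_to <- c(edges_to, i + 1L)
    edges_sym <- c(edges_sym, list(syms))
    if (tok$quantifier %in% c("plus", "star")) {
      edges_from <- c(edges_from, i + 1L); edges_to <- c(edges_to, i + 1L)
      edges_sym <- c(edges_sym, list(syms))
    }
    if (tok$quantifier %in% c("star", "optional"))
      eps[[i]] <- c(eps[[i]], i + 1L)
  }
  closure <- function(set) {
    repeat {
      nxt <- unique(c(set, unlist(eps[set])))
      if (length(nxt) == length(set)) return(sort(nxt))
      set <- nxt
    }
  }

  start_set <- closure(1L)
  state_sets <- list(start_set)
  keys <- paste(start_set, collapse = ",")
  trans <- list()
  queue <- 1L
  while (length(queue)) {
    s <- queue[[1L]]; queue <- queue[-1L]
    row <- integer(length(alphabet))
    for (a in seq_along(alphabet)) {
      tgt <- edges_to[edges_from %in% state_sets[[s]] &
                      vapply(edges_sym, function(ss) alphabet[[a]] %in% ss,
                             TRUE)]
      if (length(tgt) == 0L) { row[[a]] <- 0L; next }
      tgt <- closure(unique(tgt))
      key <- paste(tgt, collapse = ",")
      j <- match(key, keys)
      if (is.na(key) || is.na(j)) {
        state_sets <- c(state_sets, list(tgt))
        keys <- c(keys, key)
        j <- length(state_sets)
        queue <- c(queue, j)
      }
      row[[a]] <- j
    }
    trans[[s]] <- row
  }
  trans <- do.call(rbind, trans)
  colnames(trans) <- alphabet
  accepting <- vapply(state_sets, function(s) (k + 1L) %in% s, TRUE)
  structure(list(trans = trans, start = 1L, accepting = accepting,
                 alphabet = alphabet, n_states = nrow(trans),
                 pattern_text = pattern$text),
            class = "walk_dfa")
}

#' Reject sentinel for DFA transitions
#' @export
DFA_REJECT <- 0L

#' Advance a DFA by one symbol
#'
#' Pure function: returns the next state, or [DFA_REJECT] (0) when the
#' transition is undefined or the label is outside the automaton's alphabet.
#'
#' @param dfa a \code{"walk_dfa"}.
#' @param state current state (integer in 1..n_states).
#' @param label a node-type label.
#' @return next state id, or \code{DFA_REJECT}.
#' @export
dfa_step <- function(dfa, state, label) {
  if (!is.numeric(state) || state < 1L || state > dfa$n_states)
    stop("invalid DFA state: ", state)
  a <- match(label, dfa$alphabet)
  if (is.na(a)) return(DFA_REJECT)
  dfa$trans[[state, a]]
}

#' Does a type sequence match the compiled pattern?
#' @param dfa a \code{"walk_dfa"}.
#' @param labels character vector of type labels.
#' @return logical.
#' @export
dfa_matches <- function(dfa, labels) {
  s <- dfa$start
  for (lab in labels) {
    s <- dfa_step(dfa, s, lab)
    if (s == DFA_REJECT) return(FALSE)
  }
  dfa$accepting[[s]]
}

#' State stack of a consumed prefix
#'
#' Replays a valid prefix through the DFA and returns every visited state,
#' start first.  Popping the stack moves one pattern position backwards;
#' this is the bookkeeping the reverse walk mode uses.
#'
#' @param dfa a \code{"walk_dfa"}.
#' @param consumed character vector of already-consumed type labels.
#' @return integer vector of states, length \code{length(consumed) + 1}.
#' @export
dfa_state_stack <- function(dfa, consumed) {
  stack <- dfa$start
  s <- dfa$start
  for (i in seq_along(consumed)) {
    s <- dfa_step(dfa, s, consumed[[i]])
    if (s == DFA_REJECT)
      stop("invalid prefix: symbol '", consumed[[i]], "' at position ", i,
           " is rejected")
    stack <- c(stack, s)
  }
  stack
}

# labels admissible from a state (any defined transition)
dfa_admissible <- function(dfa, state) {
  dfa$alphabet[dfa$trans[state, ] != 0L]
}

# labels that move `from` to exactly `to`; the reverse walk re-enters a
# pattern position by requiring the same state path backwards
dfa_labels_between <- function(dfa, from, to) {
  dfa$alphabet[dfa$trans[from, ] == to]
}

#' @export
print.walk_dfa <- function(x, ...) {
  cat("DFA over {", paste(x$alphabet, collapse = ", "), "}\n", sep = "")
  cat("  pattern:", x$pattern_text, "\n")
  cat("  states:", x$n_states, " accepting:",
      paste(which(x$accepting), collapse = ","), "\n")
  invisible(x)
}

#' @export
print.reg_pattern <- function(x, ...) {
  cat("Regular pattern:", x$text, "\n")
  cat("  tokens:", length(x$tokens), "\n")
  invisible(x)
}
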