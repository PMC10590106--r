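#' Skip-gram embedding configuration
#'
#' The method's source papers leave the skip-gram hyperparameters open;
#' defaults follow the common word2vec/metapath2vec lineage and are all
#' config-exposed.
#'
#' @param dim embedding dimension d (default 128).
#' @param window context window half-width (default 5).
#' @param negative negative samples per positive pair (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param min_count minimum corpus frequency for a node to enter the
#'   vocabulary (default 1: knowledge-graph walks have no junk tokens).
#' @param alpha initial learning rate (default 0.025, linear decay).
#' @param seed RNG seed for initialization and sampling.
#' @param type_coarsening when TRUE, negative sampling is restricted to the
#'   coarse type group of the output node, the three-way grouping
#'   Protein / Pathway / Others used when inspecting the embedding space.
#' @param vectors which representation to return: \code{"combined"} (the
#'   sum of a node's input and output vectors, default) or \code{"input"}
#'   (the input matrix only).  The combined form makes directly
#'   co-occurring nodes measurably similar even in tiny corpora, where the
#'   input matrix alone only reflects shared contexts.
#' @return list of class \code{"embedding_config"}.
#' @export
embedding_config <- function(dim = 128L, window = 5L, negative = 5L,
                             epochs = 5L, min_count = 1L, alpha = 0.025,
                             seed = 1L, type_coarsening = FALSE,
                             vectors = c("combined", "input")) {
  stopifnot(dim >= 2L, window >= 1L, negative >= 1L, epochs >= 1L)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negative = as.integer(negative), epochs = as.integer(epochs),
                 min_count = as.integer(min_count), alpha = alpha,
                 seed = as.integer(seed),
                 type_coarsening = isTRUE(type_coarsening),
                 vectors = match.arg(vectors)),
            class = "embedding_config")
}

# coarse three-way group of a type label: Protein (resolved through the
# hierarchy), Pathway, or Others
coarse_type <- function(label, hier) {
  anc <- unlist(lapply(label, function(l) {
    a <- type_ancestors(hier, l)
    if ("Protein" %in% a) "Protein" else if ("Pathway" %in% a) "Pathway"
    else "Others"
  }))
  anc
}

#' Train skip-gram node embeddings on a walk corpus
#'
#' Standard skip-gram with negative sampling over the walk lines, trained
#' sequentially (single worker) so that a fixed seed gives identical
#' matrices across runs.  With \code{type_coarsening} on, negatives are
#' drawn within the output node's coarse group (Protein / Pathway / Others).
#'
#' @param corpus a \code{"walk_corpus"}.
#' @param config an [embedding_config()].
#' @param graph optional \code{"kg"}; required for type coarsening (it
#'   supplies the labels and hierarchy).
#' @return object of class \code{"node_embedding"}: numeric matrix
#'   \code{vectors} (vocabulary x dim, rownames = node ids, rows sorted by
#'   id) plus the config.
#' @export
train_skipgram <- function(corpus, config = embedding_config(),
                           graph = NULL) {
  stopifnot(inherits(corpus, "walk_corpus"))
  tokens <- lapply(corpus$walks, `[[`, "nodes")
  all_tok <- unlist(tokens, use.names = FALSE)
  if (length(all_tok) == 0L) stop("cannot train on an empty corpus")
  freq <- table(all_tok)
  vocab <- sort(names(freq)[freq >= config$min_count])
  if (length(vocab) == 0L) stop("min_count leaves an empty vocabulary")
  counts <- as.numeric(freq[vocab])

  grp <- integer(length(vocab))
  if (config$type_coarsening) {
    if (is.null(graph))
      stop("type_coarsening requires the graph (for node types)")
    labels <- graph$node_type[match(vocab, graph$node_id)]
    cg <- coarse_type(labels, graph$hierarchy)
    grp <- match(cg, c("Protein", "Pathway", "Others")) - 1L
  }

  sents <- lapply(tokens, function(tk) {
    m <- match(tk, vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  sents <- sents[lengths(sents) > 0L]
  mats <- .sg_train(sents, counts, config$dim, config$window,
                    config$negative, config$epochs, config$alpha,
                    grp, config$seed)
  mat <- if (identical(config$vectors, "input")) mats$input
         else mats$input + mats$output
  rownames(mat) <- vocab
  structure(list(vectors = mat, dim = config$dim, config = config),
            class = "node_embedding")
}

#' Look up embedding vectors
#' @param emb a \code{"node_embedding"}.
#' @param nodes node ids.
#' @return numeric matrix (length(nodes) x dim).
#' @export
embedding_vectors <- function(emb, nodes) {
  i <- match(nodes, rownames(emb$vectors))
  if (anyNA(i))
    stop("node(s) not in embedding vocabulary: ",
         paste(nodes[is.na(i)], collapse = ", "))
  emb$vectors[i, , drop = FALSE]
}

#' Save / load embeddings in word2vec text format
#'
#' Header line \code{"<vocab_size> <dim>"}, then one line per node:
#' \code{node_id v1 ... vd}.
#'
#' @param emb a \code{"node_embedding"}.
#' @param path file path.
#' @export
save_embeddings <- function(emb, path) {
  m <- emb$vectors
  lines <- c(paste(nrow(m), ncol(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste(rownames(m)[i],
                     paste(formatC(m[i, ], format = "g", digits = 8),
                           collapse = " ")), ""))
  writeLines(lines, path)
  invisible(emb)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[[1L]], " ", fixed = TRUE)[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop("malformed word2vec header: '", lines[[1L]], "'")
  n <- as.integer(hdr[[1L]]); d <- as.integer(hdr[[2L]])
  if (length(lines) - 1L != n)
    stop("header claims ", n, " rows, file has ", length(lines) - 1L)
  rows <- strsplit(lines[-1L], " ", fixed = TRUE)
  if (any(lengths(rows) != d + 1L))
    stop("row with wrong number of fields (expected ", d + 1L, ")")
  ids <- vapply(rows, `[[`, "", 1L)
  m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(d)))
  if (d == 1L) m <- matrix(m, ncol = 1L)
  rownames(m) <- ids
  structure(list(vectors = m, dim = d, config = NULL),
            class = "node_embedding")
}

#' PCA projection of an embedding
#'
#' Centers the vectors and projects them on the top principal components,
#' for inspecting whether coarse node types separate in embedding space.
#' When \code{groups} is given, a mean silhouette width over the projected
#' points is reported as a separation diagnostic.
#'
#' @param emb a \code{"node_embedding"}.
#' @param components number of components (<= dim).
#' @param groups optional factor/character grouping of the vocabulary
#'   (e.g. coarse types), same order as \code{rownames(emb$vectors)}.
#' @return list with \code{scores} (matrix, rownames = node ids),
#'   \code{sdev}, and \code{silhouette} (NA without groups).
#' @export
pca_projection <- function(emb, components = 2L, groups = NULL) {
  m <- emb$vectors
  if (components > ncol(m))
    stop("components (", components, ") exceeds embedding dimension (",
         ncol(m), ")")
  if (nrow(m) < 2L) stop("need at least 2 nodes")
  ctr <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0L, nv = components)
  scores <- ctr %*% sv$v
  colnames(scores) <- paste0("PC", seq_len(components))
  sil <- NA_real_
  if (!is.null(groups))
    sil <- mean_silhouette(scores, as.character(groups))
  list(scores = scores,
       sdev = sv$d[seq_len(components)] / sqrt(max(1, nrow(m) - 1L)),
       silhouette = sil)
}

# plain mean silhouette width on euclidean distances
mean_silhouette <- function(x, groups) {
  n <- nrow(x)
  if (length(unique(groups)) < 2L) return(NA_real_)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- groups == groups[[i]]
    if (sum(own) == 1L) { s[[i]] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(groups), groups[[i]]),
                    function(g) mean(d[i, groups == g]), 0))
    s[[i]] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' @export
print.node_embedding <- function(x, ...) {
  cat("Node embedding:", nrow(x$vectors), "nodes x", ncol(x$vectors),
      "dimensions\n")
  invisible(x)
}
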