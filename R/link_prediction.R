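#' Hadamard edge feature of a node pair
#'
#' The elementwise product of the two endpoint embeddings, the edge-feature
#' operator used throughout the link-prediction stage.
#'
#' @param emb a \code{"node_embedding"}.
#' @param head,tail node ids (must be in the embedding vocabulary).
#' @return numeric vector of length \code{dim}.
#' @export
hadamard_features <- function(emb, head, tail) {
  v <- embedding_vectors(emb, c(head, tail))
  v[1L, ] * v[2L, ]
}

# feature matrix for many pairs at once
hadamard_matrix <- function(emb, heads, tails) {
  embedding_vectors(emb, heads) * embedding_vectors(emb, tails)
}

#' Hold out a fraction of a relation's edges
#'
#' Removes a seeded random subset of the relation's edges from the graph,
#' to be predicted back.  The returned training graph is what walking and
#' embedding must run on, so the held-out links cannot leak into the
#' representation.
#'
#' @param graph a \code{"kg"}.
#' @param relation edge-type label to split.
#' @param holdout_fraction fraction of edges moved to the test set
#'   (default 0.5, the evaluation protocol's value).
#' @param seed integer seed for the shuffle.
#' @return list with \code{train} and \code{test} edge data.frames
#'   (columns head, relation, tail) and \code{graph_train}, the graph with
#'   test edges removed.
#' @export
split_positive_edges <- function(graph, relation, holdout_fraction = 0.5,
                                 seed = 1L) {
  stopifnot(inherits(graph, "kg"), holdout_fraction > 0,
            holdout_fraction < 1)
  idx <- which(graph$edges$relation == relation)
  if (length(idx) == 0L)
    stop("relation '", relation, "' has no edges in the graph")
  if (length(idx) < 2L)
    stop("cannot hold out from a single edge")
  n_test <- round(holdout_fraction * length(idx))
  n_test <- max(1L, min(length(idx) - 1L, n_test))
  set.seed(seed)
  test_idx <- sort(sample(idx, n_test))
  edges_train <- graph$edges[-test_idx, , drop = FALSE]
  g2 <- kg(nodes = stats::setNames(graph$node_type, graph$node_id),
           edges = edges_train, hierarchy = graph$hierarchy)
  strip <- function(e) { e <- e[c("head", "relation", "tail")]
                         row.names(e) <- NULL; e }
  list(train = strip(graph$edges[setdiff(idx, test_idx), , drop = FALSE]),
       test = strip(graph$edges[test_idx, , drop = FALSE]),
       graph_train = g2)
}

# all nodes whose type resolves (through the hierarchy) to `label`
nodes_of_type <- function(graph, label) {
  keep <- vapply(graph$node_type,
                 function(t) label %in% type_ancestors(graph, t), TRUE)
  graph$node_id[keep]
}

#' Sample closed-world negative pairs
#'
#' Under the closed-world assumption a missing edge is treated as false, so
#' negatives are typed node pairs with no edge of the relation in the
#' graph.  Pairs are distinct, seeded, and disjoint from the positive edge
#' set; additional pairs to avoid (e.g. held-out positives) can be passed
#' via \code{forbidden}.
#'
#' @param graph a \code{"kg"}.
#' @param relation edge-type label whose positives must be avoided.
#' @param head_type,tail_type type labels of the endpoints (resolved through
#'   the hierarchy).
#' @param count number of pairs.
#' @param seed integer seed.
#' @param forbidden optional data.frame with columns \code{head},
#'   \code{tail} of additional pairs to exclude.
#' @param universe optional character vector restricting both endpoints to
#'   a node subset (e.g. an embedding vocabulary).
#' @return data.frame with columns \code{head}, \code{tail}.
#' @export
sample_negatives <- function(graph, relation, head_type, tail_type, count,
                             seed = 1L, forbidden = NULL, universe = NULL) {
  heads <- nodes_of_type(graph, head_type)
  tails <- nodes_of_type(graph, tail_type)
  if (!is.null(universe)) {
    heads <- intersect(heads, universe)
    tails <- intersect(tails, universe)
  }
  pos <- graph$edges[graph$edges$relation == relation, , drop = FALSE]
  bad <- unique(c(paste0(pos$head, "\r", pos$tail),
                  paste0(pos$tail, "\r", pos$head)))
  if (!is.null(forbidden))
    bad <- unique(c(bad, paste0(forbidden$head, "\r", forbidden$tail),
                    paste0(forbidden$tail, "\r", forbidden$head)))
  all_pairs <- expand.grid(head = heads, tail = tails,
                           stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
  all_pairs <- all_pairs[all_pairs$head != all_pairs$tail, , drop = FALSE]
  key <- paste0(all_pairs$head, "\r", all_pairs$tail)
  pool <- all_pairs[!(key %in% bad), , drop = FALSE]
  pool <- pool[order(pool$head, pool$tail, method = "radix"), , drop = FALSE]
  if (nrow(pool) < count)
    stop("negative-pair space exhausted: only ", nrow(pool),
         " non-edges available, need ", count)
  set.seed(seed)
  out <- pool[sample.int(nrow(pool), count), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Build labeled link examples
#'
#' @param emb a \code{"node_embedding"}.
#' @param positives,negatives data.frames with columns \code{head},
#'   \code{tail}.
#' @return list of class \code{"link_examples"}: feature matrix \code{x},
#'   integer labels \code{y} (1 positive / 0 negative) and the pair table.
#' @export
link_examples <- function(emb, positives, negatives) {
  pairs <- rbind(data.frame(head = positives$head, tail = positives$tail,
                            label = 1L, stringsAsFactors = FALSE),
                 data.frame(head = negatives$head, tail = negatives$tail,
                            label = 0L, stringsAsFactors = FALSE))
  x <- hadamard_matrix(emb, pairs$head, pairs$tail)
  structure(list(x = x, y = pairs$label, pairs = pairs),
            class = "link_examples")
}

# ridge-logistic fit on a feature matrix; light L2 keeps the fit defined
# when the classes are linearly separable
fit_logistic <- function(x, y) {
  if (length(unique(y)) < 2L)
    stop("degenerate training set: only one class present")
  fit <- glmnet::glmnet(x, factor(y, levels = c(0L, 1L)),
                        family = "binomial", alpha = 0,
                        lambda = 1 / max(1L, nrow(x)),
                        standardize = FALSE)
  fit
}

predict_logistic <- function(fit, x) {
  as.numeric(stats::predict(fit, newx = x, type = "response"))
}

#' Train the link classifier
#'
#' Logistic regression on Hadamard features.  In \code{"binary"} mode one
#' model separates positive from negative pairs.  In \code{"one-vs-rest"}
#' mode one binary model is trained per tail class (pathway); each class's
#' negatives are drawn, seeded, from the other classes' positive pairs so
#' that the negative count matches that class's positive count.
#'
#' @param examples a \code{"link_examples"} (binary mode needs both labels;
#'   one-vs-rest uses the positive pairs' \code{tail} as the class).
#' @param mode \code{"binary"} or \code{"one-vs-rest"}.
#' @param seed integer seed (used by per-class negative draws).
#' @return object of class \code{"link_classifier"}.
#' @export
train_classifier <- function(examples, mode = c("binary", "one-vs-rest"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(examples, "link_examples"))
  if (mode == "binary") {
    fit <- fit_logistic(examples$x, examples$y)
    return(structure(list(mode = mode, fit = fit), class = "link_classifier"))
  }
  pos <- examples$pairs$label == 1L
  classes <- sort(unique(examples$pairs$tail[pos]))
  if (length(classes) < 2L)
    stop("one-vs-rest needs at least 2 tail classes")
  fits <- stats::setNames(vector("list", length(classes)), classes)
  for (k in seq_along(classes)) {
    cl <- classes[[k]]
    in_class <- pos & examples$pairs$tail == cl
    rest <- which(pos & examples$pairs$tail != cl)
    set.seed(derive_seed(seed, k, 0L))
    neg <- rest[sample.int(length(rest), min(length(rest), sum(in_class)))]
    sel <- c(which(in_class), neg)
    fits[[k]] <- fit_logistic(examples$x[sel, , drop = FALSE],
                              as.integer(in_class[sel]))
  }
  structure(list(mode = mode, fit = fits, classes = classes),
            class = "link_classifier")
}

#' Score candidate links and keep confident predictions
#'
#' @param classifier a \code{"link_classifier"}.
#' @param emb a \code{"node_embedding"}.
#' @param candidates data.frame with columns \code{head}, \code{tail}
#'   (protein, pathway).
#' @param cutoff strict confidence threshold: only predictions with
#'   confidence > cutoff are returned (default 0, i.e. all).
#' @return data.frame \code{protein}, \code{pathway}, \code{confidence},
#'   sorted by descending confidence then ids.
#' @export
predict_links <- function(classifier, emb, candidates, cutoff = 0) {
  stopifnot(inherits(classifier, "link_classifier"))
  if (nrow(candidates) == 0L)
    return(data.frame(protein = character(), pathway = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  x <- hadamard_matrix(emb, candidates$head, candidates$tail)
  if (classifier$mode == "binary") {
    conf <- predict_logistic(classifier$fit, x)
  } else {
    conf <- numeric(nrow(x))
    cl <- match(candidates$tail, classifier$classes)
    if (anyNA(cl))
      stop("candidate pathway not among one-vs-rest classes: ",
           paste(unique(candidates$tail[is.na(cl)]), collapse = ", "))
    for (k in sort(unique(cl))) {
      sel <- cl == k
      conf[sel] <- predict_logistic(classifier$fit[[k]],
                                    x[sel, , drop = FALSE])
    }
  }
  out <- data.frame(protein = candidates$head, pathway = candidates$tail,
                    confidence = conf, stringsAsFactors = FALSE)
  out <- out[out$confidence > cutoff, , drop = FALSE]
  out <- out[order(-out$confidence, out$protein, out$pathway,
                   method = "radix"), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the fraction of positive-negative pairs the
#' scores order correctly, ties counting one half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) labels.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' F1 score at a decision threshold
#' @inheritParams auc_score
#' @param threshold scores > threshold are predicted positive (default 0.5).
#' @return F1 in [0, 1] (0 when no positive prediction is made).
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  if (tp == 0L) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Evaluate link-prediction performance
#'
#' Scores the test examples with the classifier and reports AUC (rank
#' statistic) and F1 at the 0.5 threshold, plus seeded k-fold
#' cross-validation refitting the model on k-1 folds of the test examples.
#'
#' @param classifier a \code{"link_classifier"} (binary mode).
#' @param examples a \code{"link_examples"} with both labels present.
#' @param folds number of CV folds (default 10); use 0 to skip CV.
#' @param seed integer seed for the fold assignment.
#' @return list with \code{auc}, \code{f1}, \code{cv} (data.frame of
#'   per-fold auc/f1) and \code{cv_mean}.
#' @export
evaluate_links <- function(classifier, examples, folds = 10L, seed = 1L) {
  if (length(unique(examples$y)) < 2L)
    stop("test set must contain both classes")
  scores <- if (classifier$mode == "binary")
    predict_logistic(classifier$fit, examples$x)
  else stop("evaluate_links supports binary classifiers")
  out <- list(auc = auc_score(scores, examples$y),
              f1 = f1_score(scores, examples$y))
  if (folds >= 2L) {
    set.seed(seed)
    n <- length(examples$y)
    fold <- sample(rep_len(seq_len(folds), n))
    cv <- data.frame(fold = seq_len(folds), auc = NA_real_, f1 = NA_real_)
    for (k in seq_len(folds)) {
      tr <- fold != k; te <- !tr
      if (length(unique(examples$y[tr])) < 2L ||
          length(unique(examples$y[te])) < 2L) next
      fit <- fit_logistic(examples$x[tr, , drop = FALSE], examples$y[tr])
      sc <- predict_logistic(fit, examples$x[te, , drop = FALSE])
      cv$auc[[k]] <- auc_score(sc, examples$y[te])
      cv$f1[[k]] <- f1_score(sc, examples$y[te])
    }
    out$cv <- cv
    out$cv_mean <- c(auc = mean(cv$auc, na.rm = TRUE),
                     f1 = mean(cv$f1, na.rm = TRUE))
  }
  out
}

#' Replicate overlap of prediction sets
#'
#' The robustness metric: given cutoff-filtered prediction sets from
#' replicate runs, reports per protein the number of pathway predictions
#' present in every replicate and that count as a percentage of the
#' protein's unique predictions across replicates, plus the global
#' "all overlap" intersection.
#'
#' @param prediction_sets list (length >= 2) of data.frames with columns
#'   \code{protein}, \code{pathway}.
#' @return list with \code{per_protein} (data.frame protein, n_overlap,
#'   n_union, pct_overlap) and \code{all_overlap} (data.frame of pairs
#'   present in every set).
#' @export
replicate_overlap <- function(prediction_sets) {
  if (length(prediction_sets) < 2L)
    stop("need at least 2 replicate prediction sets")
  keys <- lapply(prediction_sets, function(p) {
    if (NROW(p) == 0L) character(0)
    else unique(paste0(p$protein, "\r", p$pathway))
  })
  inter <- Reduce(intersect, keys)
  uni <- Reduce(union, keys)
  split_key <- function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)
    data.frame(protein = vapply(parts, `[[`, "", 1L),
               pathway = vapply(parts, `[[`, "", 2L),
               stringsAsFactors = FALSE)
  }
  all_prot <- sort(unique(vapply(strsplit(uni, "\r", fixed = TRUE),
                                 `[[`, "", 1L)))
  per <- data.frame(protein = all_prot,
                    n_overlap = integer(length(all_prot)),
                    n_union = integer(length(all_prot)),
                    pct_overlap = numeric(length(all_prot)),
                    stringsAsFactors = FALSE)
  prot_of <- function(k) vapply(strsplit(k, "\r", fixed = TRUE), `[[`, "", 1L)
  iu <- prot_of(uni); ii <- prot_of(inter)
  for (j in seq_len(nrow(per))) {
    per$n_union[[j]] <- sum(iu == per$protein[[j]])
    per$n_overlap[[j]] <- sum(ii == per$protein[[j]])
    per$pct_overlap[[j]] <- 100 * per$n_overlap[[j]] / per$n_union[[j]]
  }
  all_df <- if (length(inter)) split_key(sort(inter))
            else data.frame(protein = character(), pathway = character(),
                            stringsAsFactors = FALSE)
  list(per_protein = per, all_overlap = all_df)
}
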