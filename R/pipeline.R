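#' Fit a pattern-walk link-prediction model
#'
#' The end-to-end estimator: hold out a fraction of the target relation's
#' edges, sample pattern-constrained inverse-degree-biased random walks on
#' the training graph, train skip-gram node embeddings on the walk corpus,
#' fit a ridge-logistic classifier on Hadamard features of positive edges
#' and closed-world negative pairs, and score the held-out edges.
#'
#' @param graph a \code{"kg"}.
#' @param pattern pattern string over type labels; the default targets
#'   protein-to-pathway links.
#' @param relation edge-type label to predict.
#' @param head_type,tail_type endpoint type labels (hierarchy-resolved) for
#'   negative sampling and candidate generation.
#' @param walk a [walk_config()]; its seed is overridden by \code{seed}.
#' @param embedding an [embedding_config()]; its seed is overridden by
#'   \code{seed}.
#' @param holdout_fraction fraction of the relation's edges held out for
#'   evaluation (default 0.5).
#' @param folds cross-validation folds run on the training examples
#'   (default 10; 0 skips CV).
#' @param seed master seed; all stage seeds derive from it.
#' @param forbidden_negatives optional data.frame (\code{head},
#'   \code{tail}) of pairs negative sampling must avoid beyond the graph's
#'   own positives - e.g. planted-but-withheld memberships when
#'   benchmarking on synthetic data.
#' @param evaluate logical: compute holdout and CV metrics (default TRUE).
#' @return object of class \code{"patternwalk"} with components
#'   \code{embedding}, \code{classifier}, \code{corpus}, \code{split},
#'   \code{metrics}, and the configurations used.  Methods: \code{print},
#'   \code{summary}, \code{predict}, \code{plot}, \code{coef}.
#' @examples
#' \donttest{
#' sim <- generate_synthetic_kg(synthetic_kg_config(proteins_per_pathway = 10))
#' fit <- patternwalk(sim$graph, seed = 17,
#'                    walk = walk_config(num_walks = 10),
#'                    embedding = embedding_config(dim = 32),
#'                    forbidden_negatives = with(sim$truth[sim$truth$dark, ],
#'                      data.frame(head = protein, tail = pathway)))
#' fit
#' }
#' @export
patternwalk <- function(graph,
                        pattern = "Protein [^Pathway]+ Protein Pathway",
                        relation = "hasPathway",
                        head_type = "Protein", tail_type = "Pathway",
                        walk = walk_config(), embedding = embedding_config(),
                        holdout_fraction = 0.5, folds = 10L, seed = 1L,
                        forbidden_negatives = NULL, evaluate = TRUE) {
  stopifnot(inherits(graph, "kg"))
  walk$seed <- derive_seed(seed, 11L, 1L)
  embedding$seed <- derive_seed(seed, 12L, 1L)

  split <- split_positive_edges(graph, relation, holdout_fraction,
                                seed = derive_seed(seed, 13L, 1L))
  dfa <- compile_dfa(pattern, alphabet = type_alphabet(graph),
                     hierarchy = graph)
  corpus <- generate_corpus(split$graph_train, dfa, walk)
  emb <- train_skipgram(corpus, embedding, graph = graph)

  vocab <- rownames(emb$vectors)
  in_vocab <- function(e) e[e$head %in% vocab & e$tail %in% vocab, ,
                            drop = FALSE]
  train_pos <- in_vocab(split$train)
  test_pos <- in_vocab(split$test)

  train_neg <- sample_negatives(graph, relation, head_type, tail_type,
                                count = nrow(train_pos),
                                seed = derive_seed(seed, 14L, 1L),
                                forbidden = forbidden_negatives,
                                universe = vocab)
  avoid <- rbind(train_neg,
                 if (is.null(forbidden_negatives))
                   train_neg[0L, ] else forbidden_negatives[c("head", "tail")])
  test_neg <- sample_negatives(graph, relation, head_type, tail_type,
                               count = nrow(test_pos),
                               seed = derive_seed(seed, 15L, 1L),
                               forbidden = avoid, universe = vocab)
  train_ex <- link_examples(emb, train_pos, in_vocab(train_neg))
  classifier <- train_classifier(train_ex, mode = "binary", seed = seed)

  metrics <- NULL
  if (evaluate && nrow(test_pos) > 0L) {
    test_ex <- link_examples(emb, test_pos, in_vocab(test_neg))
    hold <- evaluate_links(classifier, test_ex, folds = 0L)
    metrics <- list(holdout = hold[c("auc", "f1")])
    if (folds >= 2L) {
      cv <- evaluate_links(classifier, train_ex, folds = folds,
                           seed = derive_seed(seed, 16L, 1L))
      metrics$cv <- cv$cv
      metrics$cv_mean <- cv$cv_mean
    }
  }

  structure(list(graph = graph, pattern = pattern, relation = relation,
                 head_type = head_type, tail_type = tail_type,
                 dfa = dfa, corpus = corpus, embedding = emb,
                 classifier = classifier, split = split,
                 negatives = list(train = train_neg, test = test_neg),
                 metrics = metrics, seed = seed,
                 walk_config = walk, embedding_config = embedding,
                 call = match.call()),
            class = "patternwalk")
}

#' @export
print.patternwalk <- function(x, ...) {
  cat("Pattern-constrained walk link-prediction model\n")
  cat("  pattern: ", x$pattern, "\n", sep = "")
  cat("  relation:", x$relation, " corpus:", length(x$corpus$walks),
      "walks  vocab:", nrow(x$embedding$vectors), "nodes\n")
  if (!is.null(x$metrics))
    cat(sprintf("  holdout AUC %.3f  F1 %.3f\n",
                x$metrics$holdout$auc, x$metrics$holdout$f1))
  invisible(x)
}

#' @export
summary.patternwalk <- function(object, ...) {
  s <- kg_stats(object$graph)
  cat("Pattern-walk model:", object$pattern, "\n")
  cat("Graph:", s$n_nodes, "nodes,", s$n_edges, "edges;",
      "held out", nrow(object$split$test), "of",
      nrow(object$split$test) + nrow(object$split$train),
      object$relation, "edges\n")
  cat("Corpus:", length(object$corpus$walks), "walks (NW =",
      object$walk_config$num_walks, ", L =",
      object$walk_config$walk_length, ", bias =",
      object$walk_config$bias, ")\n")
  cat("Embedding:", nrow(object$embedding$vectors), "nodes x",
      object$embedding$dim, "dims\n")
  if (!is.null(object$metrics)) {
    cat(sprintf("Holdout: AUC %.3f, F1 %.3f\n",
                object$metrics$holdout$auc, object$metrics$holdout$f1))
    if (!is.null(object$metrics$cv_mean))
      cat(sprintf("%d-fold CV (training half): AUC %.3f, F1 %.3f\n",
                  nrow(object$metrics$cv), object$metrics$cv_mean[["auc"]],
                  object$metrics$cv_mean[["f1"]]))
  }
  invisible(object)
}

#' Candidate pairs for prediction
#'
#' Default candidate universe: dark-kinase nodes crossed with pathway
#' nodes, minus the graph's known positive edges.
#'
#' @param object a \code{"patternwalk"} fit.
#' @param head_label type label of candidate heads (default
#'   \code{"DarkKinase"}).
#' @return data.frame \code{head}, \code{tail}.
#' @export
candidate_pairs <- function(object, head_label = "DarkKinase") {
  g <- object$graph
  heads <- intersect(nodes_of_type(g, head_label),
                     rownames(object$embedding$vectors))
  tails <- intersect(nodes_of_type(g, object$tail_type),
                     rownames(object$embedding$vectors))
  pairs <- expand.grid(head = heads, tail = tails,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  pos <- g$edges[g$edges$relation == object$relation, , drop = FALSE]
  key <- paste0(pairs$head, "\r", pairs$tail)
  bad <- paste0(pos$head, "\r", pos$tail)
  out <- pairs[!(key %in% bad), , drop = FALSE]
  out <- out[order(out$head, out$tail, method = "radix"), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' @export
#' @rdname patternwalk
#' @param object,x a \code{"patternwalk"} fit.
#' @param candidates data.frame (\code{head}, \code{tail}); default
#'   [candidate_pairs()].
#' @param cutoff strict confidence cutoff (default 0).
#' @param ... unused.
predict.patternwalk <- function(object, candidates = NULL, cutoff = 0, ...) {
  if (is.null(candidates)) candidates <- candidate_pairs(object)
  preds <- predict_links(object$classifier, object$embedding, candidates,
                         cutoff = cutoff)
  attr(preds, "seed") <- object$seed
  attr(preds, "num_walks") <- object$walk_config$num_walks
  attr(preds, "cutoff") <- cutoff
  preds
}

#' @export
#' @rdname patternwalk
coef.patternwalk <- function(object, ...) {
  b <- stats::coef(object$classifier$fit)
  stats::setNames(as.numeric(b), rownames(b))
}

#' @export
#' @rdname patternwalk
plot.patternwalk <- function(x, ...) {
  emb <- x$embedding
  grp <- coarse_type(x$graph$node_type[match(rownames(emb$vectors),
                                             x$graph$node_id)],
                     x$graph$hierarchy)
  pc <- pca_projection(emb, 2L, groups = grp)
  cols <- c(Protein = "#1b9e77", Pathway = "#d95f02", Others = "#7570b3")
  graphics::plot(pc$scores, col = cols[grp], pch = 19, cex = 0.7,
                 xlab = "PC1", ylab = "PC2",
                 main = "Node embedding, coarse types", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(pc)
}

#' Pathway ranking for dark proteins
#'
#' For every withheld (dark) membership, scores the protein against every
#' pathway and asks whether the planted pathway scores above the median of
#' the decoys - the recovery check for sparsely annotated nodes.
#'
#' @param object a \code{"patternwalk"} fit.
#' @param truth data.frame \code{protein}, \code{pathway}, \code{dark} (as
#'   from [generate_synthetic_kg()]).
#' @return data.frame per dark protein: planted pathway, its score, the
#'   decoy median, and \code{above_median}.
#' @export
dark_recovery <- function(object, truth) {
  vocab <- rownames(object$embedding$vectors)
  darks <- truth[truth$dark & truth$protein %in% vocab, , drop = FALSE]
  pathways <- intersect(sort(unique(truth$pathway)), vocab)
  cand <- expand.grid(head = darks$protein, tail = pathways,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sc <- predict_links(object$classifier, object$embedding, cand,
                      cutoff = -1)
  key <- paste0(sc$protein, "\r", sc$pathway)
  score_of <- function(p, w) sc$confidence[[match(paste0(p, "\r", w), key)]]
  out <- darks[c("protein", "pathway")]
  out$score <- mapply(score_of, out$protein, out$pathway)
  out$median_decoy <- vapply(seq_len(nrow(out)), function(i) {
    dec <- setdiff(pathways, out$pathway[[i]])
    stats::median(vapply(dec, function(w) score_of(out$protein[[i]], w), 0))
  }, 0)
  out$above_median <- out$score > out$median_decoy
  row.names(out) <- NULL
  out
}

#' Replicate sweep of the number-of-walks hyperparameter
#'
#' Re-fits the model for every (NW, replicate) combination, keeps
#' predictions above the confidence cutoff, and summarises robustness as
#' replicate overlap: per NW the per-protein overlap across that NW's
#' replicates, and the global intersection across all runs ("all
#' overlap").
#'
#' @param graph a \code{"kg"}.
#' @param nw_values NW values to sweep (the full-scale protocol uses 10 to
#'   80).
#' @param replicates seeded replicates per NW value (default 3).
#' @param cutoff strict confidence cutoff applied to predictions
#'   (default 0.95).
#' @param seed master seed.
#' @param ... further arguments passed to [patternwalk()].
#' @return list of class \code{"patternwalk_sweep"}: \code{table} (one row
#'   per NW: mean per-protein overlap percentage and overlap pair count),
#'   \code{all_overlap} (pairs present in every run), \code{runs}.
#' @export
replicate_sweep <- function(graph, nw_values = c(10L, 20L, 40L, 80L),
                            replicates = 3L, cutoff = 0.95, seed = 1L,
                            ...) {
  stopifnot(replicates >= 2L || length(nw_values) * replicates >= 2L)
  runs <- list()
  preds <- list()
  for (i in seq_along(nw_values)) {
    for (r in seq_len(replicates)) {
      fit <- patternwalk(graph,
                         walk = walk_config(num_walks = nw_values[[i]]),
                         seed = derive_seed(seed, i, r), ...)
      p <- predict.patternwalk(fit, cutoff = cutoff)
      tag <- sprintf("nw%d_rep%d", nw_values[[i]], r)
      runs[[tag]] <- list(nw = nw_values[[i]], replicate = r,
                          seed = derive_seed(seed, i, r),
                          n_predictions = nrow(p))
      preds[[tag]] <- p
    }
  }
  if (all(vapply(preds, nrow, 0L) == 0L))
    warning("confidence cutoff ", cutoff, " leaves no prediction in any run")
  per_nw <- data.frame(nw = nw_values, mean_pct_overlap = NA_real_,
                       n_overlap = NA_integer_)
  for (i in seq_along(nw_values)) {
    sets <- preds[vapply(runs, function(r) r$nw == nw_values[[i]], TRUE)]
    ov <- replicate_overlap(sets)
    per_nw$mean_pct_overlap[[i]] <-
      if (nrow(ov$per_protein)) mean(ov$per_protein$pct_overlap) else NA_real_
    per_nw$n_overlap[[i]] <- nrow(ov$all_overlap)
  }
  all_ov <- replicate_overlap(preds)$all_overlap
  structure(list(table = per_nw, all_overlap = all_ov, runs = runs,
                 predictions = preds, cutoff = cutoff),
            class = "patternwalk_sweep")
}

#' @export
print.patternwalk_sweep <- function(x, ...) {
  cat("Replicate sweep (cutoff", x$cutoff, ")\n")
  print(x$table)
  cat("All-overlap predictions:", nrow(x$all_overlap), "\n")
  invisible(x)
}

#' Write / read a prediction table
#'
#' Tab-separated \code{protein<TAB>pathway<TAB>confidence} with \code{#}
#' metadata header lines carrying seed, NW and cutoff.
#'
#' @param preds prediction data.frame from [predict.patternwalk()].
#' @param path file path.
#' @export
write_predictions <- function(preds, path) {
  hdr <- c(paste0("# seed=", attr(preds, "seed")),
           paste0("# num_walks=", attr(preds, "num_walks")),
           paste0("# cutoff=", attr(preds, "cutoff")),
           "protein\tpathway\tconfidence")
  body <- sprintf("%s\t%s\t%.6f", preds$protein, preds$pathway,
                  preds$confidence)
  writeLines(c(hdr, body), path)
  invisible(preds)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  for (m in meta) {
    kv <- strsplit(sub("^#\\s*", "", m), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) attr(tab, kv[[1L]]) <- utils::type.convert(
      kv[[2L]], as.is = TRUE)
  }
  tab
}

#' Run the pipeline end to end and write a manifest
#'
#' Executes the stages build -> walk -> embed -> train -> predict ->
#' evaluate, writing each artifact under \code{out_dir} with a manifest of
#' paths, checksums and seeds.  A failing stage aborts with the stage name.
#' Re-running with the same inputs rewrites every artifact byte-identically
#' (all stages are seeded), so the manifest checksums are stable.
#'
#' @param graph a \code{"kg"}, or a list with paths \code{triples},
#'   \code{node_types} and optionally \code{hierarchy}.
#' @param out_dir output directory.
#' @param cutoff confidence cutoff for the written prediction table.
#' @param ... passed to [patternwalk()].
#' @return the manifest (named list), invisibly written as
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(graph, out_dir, cutoff = 0.95, ...) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  g <- stage("build", {
    if (inherits(graph, "kg")) graph
    else load_kg(graph$triples, graph$node_types, graph$hierarchy)
  })
  fit <- stage("fit", patternwalk(g, ...))
  paths <- list(corpus = file.path(out_dir, "corpus.txt"),
                embeddings = file.path(out_dir, "embeddings.w2v"),
                predictions = file.path(out_dir, "predictions.tsv"),
                metrics = file.path(out_dir, "metrics.json"))
  stage("walk", write_corpus(fit$corpus, paths$corpus))
  stage("embed", save_embeddings(fit$embedding, paths$embeddings))
  preds <- stage("predict", predict.patternwalk(fit, cutoff = cutoff))
  stage("predict", write_predictions(preds, paths$predictions))
  stage("evaluate", jsonlite::write_json(
    list(holdout = fit$metrics$holdout,
         cv_mean = as.list(fit$metrics$cv_mean)),
    paths$metrics, auto_unbox = TRUE, digits = NA))
  manifest <- list(seed = fit$seed,
                   pattern = fit$pattern,
                   graph_fingerprint = kg_fingerprint(g),
                   files = lapply(paths, function(p)
                     list(path = p,
                          md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
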