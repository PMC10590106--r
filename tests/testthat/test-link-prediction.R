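fake_emb <- function(m) structure(list(vectors = m, dim = ncol(m)),
                                  class = "node_embedding")

test_that("Hadamard features are the elementwise product", {
  m <- rbind(a = c(1, 2, 3), b = c(4, 5, 6), z = c(0, 0, 0),
             o = c(1, 1, 1))
  emb <- fake_emb(m)
  expect_equal(hadamard_features(emb, "a", "b"), c(4, 10, 18))
  expect_equal(hadamard_features(emb, "a", "z"), c(0, 0, 0))
  expect_equal(hadamard_features(emb, "a", "o"), c(1, 2, 3))
  expect_error(hadamard_features(emb, "a", "nope"), "vocabulary")
})

test_that("edge holdout splits are disjoint, sized and reproducible", {
  prot <- sprintf("p%d", 1:10)
  g <- kg(nodes = c(stats::setNames(rep("Protein", 10), prot),
                    w1 = "Pathway"),
          edges = data.frame(head = prot, relation = "hasPathway",
                             tail = "w1"))
  sp <- split_positive_edges(g, "hasPathway", 0.5, seed = 3L)
  expect_equal(nrow(sp$train), 5L)
  expect_equal(nrow(sp$test), 5L)
  expect_length(intersect(paste(sp$train$head), paste(sp$test$head)), 0L)
  expect_equal(nrow(sp$graph_train$edges), 5L)
  sp2 <- split_positive_edges(g, "hasPathway", 0.5, seed = 3L)
  expect_identical(sp$test, sp2$test)

  g1 <- kg(nodes = c(p1 = "Protein", w1 = "Pathway"),
           edges = data.frame(head = "p1", relation = "hasPathway",
                              tail = "w1"))
  expect_error(split_positive_edges(g1, "hasPathway"), "single edge")
  expect_error(split_positive_edges(g, "nope"), "no edges")
})

test_that("negative sampling avoids positives and errors on exhaustion", {
  g <- kg(nodes = c(p1 = "Protein", p2 = "Protein", w1 = "Pathway",
                    w2 = "Pathway"),
          edges = data.frame(head = c("p1", "p2"), relation = "hasPathway",
                             tail = c("w1", "w2")))
  neg <- sample_negatives(g, "hasPathway", "Protein", "Pathway", 2L,
                          seed = 1L)
  expect_setequal(paste(neg$head, neg$tail), c("p1 w2", "p2 w1"))
  expect_error(sample_negatives(g, "hasPathway", "Protein", "Pathway", 3L),
               "exhausted")

  # brute-force disjointness on random bipartite graphs
  for (seed in 1:3) {
    set.seed(seed)
    prot <- sprintf("p%d", 1:12); pw <- sprintf("w%d", 1:6)
    e <- expand.grid(head = prot, tail = pw, stringsAsFactors = FALSE)
    e <- e[sample(nrow(e), 30L), ]
    g2 <- kg(nodes = c(stats::setNames(rep("Protein", 12), prot),
                       stats::setNames(rep("Pathway", 6), pw)),
             edges = data.frame(head = e$head, relation = "hasPathway",
                                tail = e$tail))
    neg <- sample_negatives(g2, "hasPathway", "Protein", "Pathway", 20L,
                            seed = seed)
    expect_equal(nrow(neg), 20L)
    expect_equal(anyDuplicated(paste(neg$head, neg$tail)), 0L)
    expect_length(intersect(paste(neg$head, neg$tail),
                            paste(e$head, e$tail)), 0L)
  }
})

test_that("classifier separates separable features and errors on one class", {
  set.seed(5)
  m <- rbind(matrix(rnorm(40 * 8, 2), ncol = 8),
             matrix(rnorm(40 * 8, -2), ncol = 8))
  rownames(m) <- sprintf("n%02d", 1:80)
  emb <- fake_emb(abs(m) + 0.1)
  ex <- structure(list(x = m, y = rep(c(1L, 0L), each = 40L),
                       pairs = data.frame(head = rownames(m), tail = "w",
                                          label = rep(c(1L, 0L),
                                                      each = 40L))),
                  class = "link_examples")
  clf <- train_classifier(ex, "binary")
  sc <- patternwalk:::predict_logistic(clf$fit, m)
  expect_equal(mean((sc > 0.5) == (ex$y == 1L)), 1.0)

  ex1 <- ex; ex1$y <- rep(1L, 80L)
  expect_error(train_classifier(ex1, "binary"), "one class")
})

test_that("labels independent of features give chance-level CV AUC", {
  set.seed(6)
  x <- matrix(rnorm(400 * 10), ncol = 10)
  y <- rep(c(0L, 1L), 200L)
  ex <- structure(list(x = x, y = y,
                       pairs = data.frame(head = "h", tail = "t",
                                          label = y)),
                  class = "link_examples")
  clf <- train_classifier(ex, "binary")
  ev <- evaluate_links(clf, ex, folds = 10L, seed = 6L)
  expect_gt(ev$cv_mean[["auc"]], 0.4)
  expect_lt(ev$cv_mean[["auc"]], 0.6)
})

test_that("one-vs-rest trains one model per pathway class", {
  set.seed(7)
  pw <- rep(c("w1", "w2", "w3"), each = 20L)
  centers <- matrix(rnorm(3 * 6, sd = 4), nrow = 3)
  x <- centers[match(pw, c("w1", "w2", "w3")), ] + rnorm(60 * 6, sd = 0.3)
  ex <- structure(list(x = x, y = rep(1L, 60L),
                       pairs = data.frame(head = sprintf("p%d", 1:60),
                                          tail = pw, label = 1L)),
                  class = "link_examples")
  clf <- train_classifier(ex, "one-vs-rest", seed = 7L)
  expect_length(clf$fit, 3L)
  expect_equal(clf$classes, c("w1", "w2", "w3"))
})

test_that("prediction cutoff is a strict inequality", {
  set.seed(8)
  m <- rbind(matrix(rnorm(30 * 4, 3), ncol = 4),
             matrix(rnorm(30 * 4, -3), ncol = 4))
  rownames(m) <- c(sprintf("p%02d", 1:30), sprintf("q%02d", 1:30))
  w <- matrix(1, 1, 4, dimnames = list("w1", NULL))
  emb <- fake_emb(rbind(m, w))
  ex <- structure(list(x = m, y = rep(c(1L, 0L), each = 30L),
                       pairs = data.frame(head = rownames(m), tail = "w1",
                                          label = rep(c(1L, 0L),
                                                      each = 30L))),
                  class = "link_examples")
  clf <- train_classifier(ex, "binary")
  cand <- data.frame(head = rownames(m), tail = "w1")
  all_preds <- predict_links(clf, emb, cand, cutoff = 0)
  expect_equal(nrow(all_preds), 60L)
  expect_false(is.unsorted(rev(all_preds$confidence)))
  expect_equal(nrow(predict_links(clf, emb, cand, cutoff = 1.0)), 0L)
  # cutoff exactly at an attained confidence excludes that record
  cmax <- max(all_preds$confidence)
  at_max <- predict_links(clf, emb, cand, cutoff = cmax)
  expect_false(cmax %in% at_max$confidence)
})

test_that("AUC matches hand-computed and brute-force pairwise values", {
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(c(0.9, 0.7, 0.8, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(f1_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")

  set.seed(9)
  for (rep in 1:20) {
    n <- sample(4:50, 1L)
    y <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
    s <- round(stats::runif(n), 2L) # rounding forces ties
    expect_equal(auc_score(s, y), brute_auc(s, y))
  }
  skip_if_not_installed("pROC")
  set.seed(10)
  y <- sample(0:1, 40L, replace = TRUE, prob = c(0.5, 0.5))
  s <- stats::runif(40L)
  expect_equal(auc_score(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))))
})

test_that("replicate overlap computes intersections and percentages", {
  mk <- function(...) data.frame(protein = "k1", pathway = c(...))
  ov <- replicate_overlap(list(mk("A", "B"), mk("A", "C"), mk("A")))
  expect_equal(nrow(ov$all_overlap), 1L)
  expect_equal(ov$all_overlap$pathway, "A")
  expect_equal(ov$per_protein$n_overlap, 1L)
  expect_equal(ov$per_protein$n_union, 3L)
  expect_equal(ov$per_protein$pct_overlap, 100 / 3)

  same <- list(mk("A", "B"), mk("A", "B"), mk("A", "B"))
  ovs <- replicate_overlap(same)
  expect_equal(ovs$per_protein$pct_overlap, 100)

  disj <- list(mk("A"), mk("B"))
  ovd <- replicate_overlap(disj)
  expect_equal(ovd$per_protein$n_overlap, 0L)
  expect_equal(nrow(ovd$all_overlap), 0L)
  expect_error(replicate_overlap(list(mk("A"))), "at least 2")
})
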