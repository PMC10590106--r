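# pattern used on the A/B/C/D fixtures: start A, cross non-B's, end A B
fix_dfa <- function(alpha = c("A", "B", "C", "D"))
  compile_dfa("A [^B]+ A B", alpha)

test_that("inverse-degree bias yields the analytic step distribution", {
  g <- star_kg()
  dfa <- compile_dfa("A B+ A", c("A", "B", "C"))
  s1 <- dfa_step(dfa, dfa$start, "A")
  td <- transition_distribution(g, dfa, s1, "h")
  # neighbor degrees 1, 2, 4 -> inverse-degree weights 4/7, 2/7, 1/7
  expect_equal(td$neighbor, c("n1", "n2", "n4"))
  expect_equal(td$probability, c(4, 2, 1) / 7)
  expect_equal(sum(td$probability), 1)
})

test_that("disallowed neighbor types get zero mass and are not normalized over", {
  g <- relation_star_kg() # relation a: u(B) admissible, z1/z2(D) not; b: v(B)
  dfa <- compile_dfa("A B+ A", c("A", "B", "C", "D"))
  s1 <- dfa_step(dfa, dfa$start, "A")
  td <- transition_distribution(g, dfa, s1, "c")
  expect_false(any(td$neighbor %in% c("z1", "z2")))
  # g(a) = 3/4, g(b) = 1/4, one admissible unit-ish neighbor each
  expect_equal(td$probability[td$relation == "a"], 0.75)
  expect_equal(td$probability[td$relation == "b"], 0.25)
  expect_equal(sum(td$probability), 1)
})

test_that("transition probabilities are exact rationals summing to one", {
  for (seed in c(11, 12)) {
    g <- random_kg(seed)
    dfa <- fix_dfa()
    set.seed(seed)
    for (v in sample(g$node_id[g$degree > 0], 10)) {
      st <- dfa_step(dfa, dfa$start, g$node_type[match(v, g$node_id)])
      if (st == DFA_REJECT) st <- 2L
      td <- transition_distribution(g, dfa, st, v)
      ex <- exact_two_stage(g, dfa, st, v)
      if (is.null(ex)) {
        expect_equal(nrow(td), 0L)
        next
      }
      # integer-arithmetic conservation: relation weights and per-relation
      # neighbor weights each sum to their exact denominators
      expect_equal(sum(td$probability), 1, tolerance = 1e-12)
      agg <- stats::aggregate(list(num = ex$num),
                              by = list(relation = ex$relation,
                                        neighbor = ex$neighbor,
                                        den = ex$den), FUN = sum)
      agg <- agg[order(agg$relation, agg$neighbor), ]
      expect_equal(td$probability, agg$num / agg$den, tolerance = 1e-12)
    }
  }
})

test_that("g(r) proportions match brute-force edge counts", {
  g <- random_kg(21)
  for (v in g$node_id[g$degree > 0][1:10]) {
    pr <- relation_profile(g, v)
    e <- g$edges
    cnt <- table(c(e$relation[e$head == v], e$relation[e$tail == v]))
    expect_equal(pr[names(cnt)], as.numeric(cnt) / sum(cnt),
                 ignore_attr = TRUE)
  }
})

test_that("walks on the chain fixture follow the documented trace", {
  g <- chain_kg()
  dfa <- compile_dfa("Protein [^Pathway]+ Protein Pathway",
                     type_alphabet(g))
  # the one stochastic choice is at g1 (both p1 and p2 are admissible
  # Proteins); on the branch that advances to p2 the rest of the walk is
  # forced: acceptance at w1, and with budget left the re-emission plus a
  # reverse step to w1's only Protein neighbor
  seeds <- 1:100
  hit <- NA
  for (s in seeds) {
    set.seed(s)
    w4 <- generate_walk(g, dfa, "p1", walk_config(walk_length = 4L))
    if (identical(w4$nodes, c("p1", "g1", "p2", "w1"))) { hit <- s; break }
    expect_true(isTRUE(validate_walk(g, dfa, w4))) # other sampled branches
  }
  expect_false(is.na(hit))
  expect_equal(w4$phase, rep("forward", 4L))

  set.seed(hit)
  w6 <- generate_walk(g, dfa, "p1", walk_config(walk_length = 6L))
  expect_equal(w6$nodes, c("p1", "g1", "p2", "w1", "w1", "p2"))
  expect_equal(w6$phase, c(rep("forward", 4L), "reverse", "reverse"))

  expect_error(generate_walk(g, dfa, "w1", walk_config()),
               "not admissible")
})

test_that("corpus generation counts, determinism and seed sensitivity", {
  g <- random_kg(31, n_nodes = 40L, n_edges = 120L)
  dfa <- fix_dfa()
  cfg <- walk_config(walk_length = 5L, num_walks = 10L, seed = 3L)
  co <- generate_corpus(g, dfa, cfg)
  expect_equal(length(co$walks), 10L * sum(g$node_type == "A"))

  co2 <- generate_corpus(g, dfa, cfg)
  expect_identical(lapply(co$walks, `[[`, "nodes"),
                   lapply(co2$walks, `[[`, "nodes"))

  co3 <- generate_corpus(g, dfa, walk_config(walk_length = 5L,
                                             num_walks = 10L, seed = 4L))
  expect_false(identical(lapply(co$walks, `[[`, "nodes"),
                         lapply(co3$walks, `[[`, "nodes")))

  expect_equal(walk_config()$num_walks, 40L)
  expect_error(generate_corpus(g, dfa,
                               walk_config(start_types = "Pathway")),
               "no eligible start")
})

test_that("start types are hierarchy-resolved", {
  g <- kg(nodes = c(d1 = "DarkKinase", g1 = "GOTerm", p2 = "Protein",
                    w1 = "Pathway"),
          edges = data.frame(head = c("d1", "g1", "p2"),
                             relation = c("hasGO", "hasGO", "hasPathway"),
                             tail = c("g1", "p2", "w1")),
          hierarchy = c(DarkKinase = "Protein"))
  dfa <- compile_dfa("Protein [^Pathway]+ Protein Pathway",
                     type_alphabet(g), g)
  co <- generate_corpus(g, dfa, walk_config(num_walks = 2L,
                                            start_types = "Protein"))
  starts <- unique(vapply(co$walks, function(w) w$nodes[[1L]], ""))
  expect_setequal(starts, c("d1", "p2"))
})

test_that("corpus round trip and empty corpus writing", {
  g <- chain_kg()
  dfa <- compile_dfa("Protein [^Pathway]+ Protein Pathway",
                     type_alphabet(g))
  co <- generate_corpus(g, dfa, walk_config(num_walks = 3L, seed = 9L))
  td <- withr::local_tempdir()
  p <- file.path(td, "corpus.txt")
  write_corpus(co, p)
  expect_equal(readLines(p)[1L],
               paste(co$walks[[1L]]$nodes, collapse = " "))
  back <- read_corpus(p, graph = g)
  expect_equal(lapply(back$walks, `[[`, "nodes"),
               lapply(co$walks, `[[`, "nodes"))
  expect_equal(back$seed, co$seed)

  empty <- structure(list(walks = list(), seed = 1L,
                          config = walk_config(), pattern_text = "x",
                          graph_fingerprint = "f"),
                     class = "walk_corpus")
  write_corpus(empty, file.path(td, "empty.txt"))
  expect_length(readLines(file.path(td, "empty.txt")), 0L)
  expect_true(file.exists(file.path(td, "empty.txt.meta.json")))
})

test_that("sampled walks always respect the pattern and reverse rule", {
  dfa <- fix_dfa()
  n_checked <- 0L
  for (seed in c(41, 42)) {
    g <- random_kg(seed, n_nodes = 50L, n_edges = 160L)
    co <- generate_corpus(g, dfa, walk_config(walk_length = 6L,
                                              num_walks = 20L, seed = seed))
    for (w in co$walks) {
      v <- validate_walk(g, dfa, w)
      if (!isTRUE(v)) fail(paste("invalid walk:", v))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 400L)
})

test_that("empirical first-step frequencies match the distribution", {
  g <- star_kg()
  dfa <- compile_dfa("A B+ A", c("A", "B", "C"))
  cfg <- walk_config(walk_length = 2L, num_walks = 20000L, seed = 5L)
  co <- generate_corpus(g, dfa, cfg)
  hub_walks <- Filter(function(w) w$nodes[[1L]] == "h", co$walks)
  first <- vapply(hub_walks, function(w) w$nodes[[2L]], "")
  freq <- table(factor(first, levels = c("n1", "n2", "n4"))) /
    length(first)
  p <- c(4, 2, 1) / 7
  se <- sqrt(p * (1 - p) / length(first))
  expect_true(all(abs(as.numeric(freq) - p) < 3 * se))
})

test_that("inverse-degree bias suppresses hubs relative to uniform choice", {
  sim <- generate_synthetic_kg(small_sim_config())
  g <- sim$graph
  dfa <- compile_dfa("Protein [^Pathway]+ Protein Pathway",
                     type_alphabet(g), g)
  mean_visited_degree <- function(bias) {
    co <- generate_corpus(g, dfa, walk_config(num_walks = 5L, seed = 7L,
                                              bias = bias))
    visited <- unlist(lapply(co$walks, function(w) w$nodes[-1L]))
    mean(g$degree[match(visited, g$node_id)])
  }
  expect_lt(mean_visited_degree("two-stage"),
            mean_visited_degree("uniform"))
})

test_that("single-stage bias mode normalizes g(r)/degree jointly", {
  g <- relation_star_kg()
  dfa <- compile_dfa("A B+ A", c("A", "B", "C", "D"))
  s1 <- dfa_step(dfa, dfa$start, "A")
  td <- transition_distribution(g, dfa, s1, "c", bias = "single-stage")
  # weights: u gets g(a)/deg(u) = (3/4)/1, v gets (1/4)/1
  expect_equal(td$probability[td$neighbor == "u"], 0.75)
  expect_equal(td$probability[td$neighbor == "v"], 0.25)
  expect_equal(sum(td$probability), 1)
})
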