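test_that("construction, loading and basic indices work on small graphs", {
  g <- kg(nodes = c(p1 = "Protein", w1 = "Pathway"),
          edges = data.frame(head = "p1", relation = "hasPathway",
                             tail = "w1"))
  expect_equal(kg_degree(g, "p1"), 1L)
  expect_equal(kg_degree(g, "w1"), 1L)

  # empty edge set: isolated nodes survive
  td <- withr::local_tempdir()
  writeLines(character(0), file.path(td, "t.tsv"))
  writeLines(c("a\tA", "b\tB", "c\tA"), file.path(td, "n.tsv"))
  g2 <- load_kg(file.path(td, "t.tsv"), file.path(td, "n.tsv"))
  expect_equal(length(g2$node_id), 3L)
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(kg_degree(g2, "a"), 0L)

  # referential integrity error names the offending node
  writeLines("a\tr\tx9", file.path(td, "t2.tsv"))
  expect_error(load_kg(file.path(td, "t2.tsv"), file.path(td, "n.tsv")),
               "x9")

  # malformed row reported with its line number
  writeLines(c("# comment", "a\tr\tb", "only-two\tfields"),
             file.path(td, "t3.tsv"))
  expect_error(load_kg(file.path(td, "t3.tsv"), file.path(td, "n.tsv")),
               "line 3")

  expect_error(kg(nodes = c(a = "A"),
                  edges = data.frame(head = "a", relation = "r",
                                     tail = "a")),
               "self-loop")
})

test_that("neighbors enumerates incident edges deterministically", {
  g <- kg(nodes = c(c = "T", n1 = "T", n2 = "T", n3 = "T", iso = "T"),
          edges = data.frame(head = c("c", "c", "c"),
                             relation = c("a", "a", "b"),
                             tail = c("n1", "n2", "n3")))
  nb <- kg_neighbors(g, "c")
  expect_equal(nb$relation, c("a", "a", "b"))
  expect_equal(nb$neighbor, c("n1", "n2", "n3"))
  expect_equal(kg_neighbors(g, "c", relation = "b")$neighbor, "n3")
  expect_equal(nrow(kg_neighbors(g, "iso")), 0L)
  expect_error(kg_neighbors(g, "nope"), "unknown node")

  expect_equal(kg_degree(g, "c"), 3L)
  expect_equal(kg_degree(g, "n1"), 1L)
  expect_equal(kg_degree(g, "iso"), 0L)
})

test_that("relation profile gives per-relation edge proportions", {
  g <- kg(nodes = c(v = "T", a1 = "T", a2 = "T", a3 = "T", b1 = "T",
                    s = "T"),
          edges = data.frame(head = c("v", "v", "v", "v", "s"),
                             relation = c("a", "a", "a", "b", "a"),
                             tail = c("a1", "a2", "a3", "b1", "a1")))
  expect_equal(relation_profile(g, "v"), c(a = 0.75, b = 0.25))
  expect_equal(relation_profile(g, "s"), c(a = 1.0))
  expect_error(relation_profile(kg(nodes = c(x = "T")), "x"), "degree-0")

  # 13 relations once each: every proportion 1/13 (counting oracle)
  rels <- sprintf("rel%02d", 1:13)
  nbrs <- sprintf("m%02d", 1:13)
  g13 <- kg(nodes = c(c(v = "T"), stats::setNames(rep("T", 13), nbrs)),
            edges = data.frame(head = "v", relation = rels, tail = nbrs))
  pr <- relation_profile(g13, "v")
  expect_equal(unname(pr), rep(1 / 13, 13))
  expect_equal(sum(pr), 1)
})

test_that("schema view projects instance edges through the type maps", {
  g <- kg(nodes = c(p1 = "Protein", w1 = "Pathway", p2 = "Protein"),
          edges = data.frame(head = c("p1", "p1"),
                             relation = c("hasPathway", "interactsWith"),
                             tail = c("w1", "p2")))
  s <- schema_view(g)
  expect_true(any(s$source_type == "Protein" & s$relation == "hasPathway" &
                  s$target_type == "Pathway"))
  # PPI projects to a loop edge at the Protein type
  expect_true(any(s$source_type == "Protein" & s$target_type == "Protein" &
                  s$relation == "interactsWith"))

  # randomized fixture equals the brute-force projection
  gr <- random_kg(101, n_edges = 100L)
  s2 <- schema_view(gr)
  ty <- function(v) gr$node_type[match(v, gr$node_id)]
  brute <- unique(paste(ty(gr$edges$head), gr$edges$relation,
                        ty(gr$edges$tail)))
  expect_setequal(paste(s2$source_type, s2$relation, s2$target_type), brute)
  expect_equal(anyDuplicated(s2), 0L)
})

test_that("degree/neighbor consistency and symmetry hold on random graphs", {
  for (seed in c(1, 2, 3)) {
    g <- random_kg(seed)
    for (v in sample(g$node_id, 15)) {
      nb <- kg_neighbors(g, v)
      expect_equal(kg_degree(g, v), nrow(nb))
    }
    e <- g$edges[sample(nrow(g$edges), 20), ]
    for (i in seq_len(nrow(e))) {
      expect_true(e$tail[i] %in% kg_neighbors(g, e$head[i])$neighbor)
      expect_true(e$head[i] %in% kg_neighbors(g, e$tail[i])$neighbor)
    }
  }
})

test_that("write/load round trip preserves nodes, edge multiset and schema", {
  g <- random_kg(7, n_nodes = 30L, n_edges = 60L)
  td <- withr::local_tempdir()
  write_kg(g, file.path(td, "t.tsv"), file.path(td, "n.tsv"))
  g2 <- load_kg(file.path(td, "t.tsv"), file.path(td, "n.tsv"))
  expect_equal(g2$node_id, g$node_id)
  expect_equal(g2$node_type, g$node_type)
  key <- function(e) sort(paste(e$head, e$relation, e$tail))
  expect_equal(key(g2$edges), key(g$edges))
  expect_equal(schema_view(g2), schema_view(g))
})

test_that("type hierarchy resolves through parents and rejects cycles", {
  g <- kg(nodes = c(d1 = "DarkKinase", w = "Pathway"),
          hierarchy = c(DarkKinase = "Protein", LightKinase = "Protein"))
  expect_equal(type_ancestors(g, "DarkKinase"), c("DarkKinase", "Protein"))
  expect_true("Protein" %in% type_alphabet(g))
  expect_error(kg(nodes = c(a = "A"), hierarchy = c(A = "B", B = "A")),
               "cycle")
})

test_that("kg stats summarises per-type and per-relation structure", {
  g <- random_kg(5)
  s <- kg_stats(g)
  expect_equal(s$n_edges, nrow(g$edges))
  expect_equal(sum(s$node_counts), length(g$node_id))
  expect_equal(sum(s$edge_counts), nrow(g$edges))
})
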