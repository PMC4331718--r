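test_that("maximal clique enumeration handles canonical small cases", {
  tri <- net_from_pairs(c("A B", "A C", "B C", "C D"))
  expect_equal(enumerate_maximal_cliques(tri), list(c("A", "B", "C")))

  k4 <- net_from_pairs(c("A B", "A C", "A D", "B C", "B D", "C D"))
  expect_equal(enumerate_maximal_cliques(k4), list(c("A", "B", "C", "D")))

  path <- net_from_pairs(c("A B", "B C"))
  expect_equal(enumerate_maximal_cliques(path), list())
  expect_error(enumerate_maximal_cliques(path, min_size = 1L), "min_size")
})

test_that("enumeration agrees with the brute-force subset oracle", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(6:12, 1L)
    edges <- random_typed_edges(n, stats::runif(1, 0.2, 0.6))
    if (is.null(edges)) next
    net <- build_network(edges)
    expect_identical(enumerate_maximal_cliques(net),
                     brute_maximal_cliques(net))
  }
})

test_that("common attribute sets intersect member annotations", {
  net <- worked_example_network()
  expect_equal(common_attribute_set(net, c("P2", "P3", "P5")),
               c("GS1", "GS2"))
  expect_equal(common_attribute_set(net, "P2"), c("GS1", "GS2"))
  expect_equal(common_attribute_set(net, c("P2", "P6")), "GS1")
  expect_error(common_attribute_set(net, character()), "empty")
  expect_error(common_attribute_set(net, "NOPE"), "not in the network")

  bare <- net_from_pairs(c("A B", "A C", "B C"),
                         annotations = ann("A", "GS1", "B", "GS1"))
  expect_equal(common_attribute_set(bare, c("A", "B", "C")), character())
})

test_that("structural correlation matches the printed worked values", {
  net <- worked_example_network()
  expect_equal(structural_correlation(net, "GS1"), 0.625)
  expect_equal(structural_correlation(net, "GS3"), 0)
  expect_equal(structural_correlation(net, c("GS1", "GS2")), 1)
  expect_equal(structural_correlation(net, "ABSENT"), 0)

  tri <- net_from_pairs(c("A B", "A C", "B C"),
                        annotations = ann("A", "GS1", "B", "GS1", "C", "GS1"))
  expect_equal(structural_correlation(tri, "GS1"), 1)
})

test_that("eta agrees with the triangle-vertex oracle on random graphs", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(6:12, 1L)
    edges <- random_typed_edges(n, stats::runif(1, 0.2, 0.6))
    if (is.null(edges)) next
    vs <- unique(c(edges$protein_a, edges$protein_b))
    net <- suppressMessages(build_network(edges, random_annotations(vs)))
    ## whole network: eta(empty S) is the overall triangle-vertex fraction
    expect_equal(structural_correlation(net, character()),
                 length(brute_triangle_vertices(net)) / length(net$vertices))
    for (S in net$attr_terms) {
      sub <- induced_subgraph(net, S)
      expected <- if (length(sub$vertices) == 0L) 0 else
        length(brute_triangle_vertices(sub)) / length(sub$vertices)
      expect_equal(structural_correlation(net, S), expected)
    }
  }
})

test_that("attributed density matches hand arithmetic", {
  both <- net_from_pairs(c("A B", "A C", "B C"), type = "T1")
  both2 <- suppressMessages(build_network(rbind(
    data.frame(protein_a = c("A", "A", "B"), protein_b = c("B", "C", "C"),
               source_type = "T1"),
    data.frame(protein_a = c("A", "A", "B"), protein_b = c("B", "C", "C"),
               source_type = "T2"))))
  expect_equal(attributed_density(both2, c("A", "B", "C"), w64), 1.0)
  expect_equal(attributed_density(both2, c("A", "B", "C"),
                                  source_weights(c(T1 = 0.9, T2 = 0.1))), 1.0)

  net <- worked_example_network()
  expect_equal(attributed_density(net, c("P2", "P3", "P5"), w64), 0.867,
               tolerance = 5e-4)
  expect_equal(attributed_density(net, c("P2", "P3", "P4", "P5"), w64), 0.833,
               tolerance = 5e-4)
  expect_equal(attributed_density(net, c("P2", "P5", "P6"), w64), 0.667,
               tolerance = 5e-4)
  expect_error(attributed_density(net, "P2", w64), "at least 2")
})

test_that("clique scores compose eta, size, |S| and density", {
  net <- worked_example_network()
  oc <- clique_score(net, c("P2", "P3", "P4", "P5"), w64)
  expect_equal(oc$S, c("GS1", "GS2"))
  expect_equal(oc$eta, 1)
  expect_equal(oc$n_edges, 6)
  expect_equal(oc$score, 1 * 4 * 2 * oc$density)

  ## a clique with an unannotated member scores zero
  bare <- net_from_pairs(c("A B", "A C", "B C"),
                         annotations = ann("A", "GS1", "B", "GS1"))
  expect_equal(clique_score(bare, c("A", "B", "C"), w55)$score, 0)

  expect_error(clique_score(net, c("P2", "P3", "P6"), w64), "not a clique")
  expect_error(clique_score(net, c("P2", "P3"), w64), ">= 3")
})

test_that("clique scores are invariant under vertex relabeling", {
  set.seed(303)
  edges <- random_typed_edges(9, 0.5)
  vs <- sort(unique(c(edges$protein_a, edges$protein_b)))
  ## every vertex shares GS0 so any triangle is a scoring candidate
  anns <- rbind(data.frame(protein = vs, go_slim = "GS0"),
                random_annotations(vs))
  net <- suppressMessages(build_network(edges, anns))
  cands <- generate_candidates(net, w64)
  expect_gt(length(cands), 0L)

  relab <- stats::setNames(sprintf("Z%02d", rev(seq_along(vs))), vs)
  edges2 <- data.frame(protein_a = relab[edges$protein_a],
                       protein_b = relab[edges$protein_b],
                       source_type = edges$source_type)
  anns2 <- data.frame(protein = relab[anns$protein], go_slim = anns$go_slim)
  net2 <- suppressMessages(build_network(edges2, anns2))
  for (oc in cands) {
    oc2 <- clique_score(net2, unname(relab[oc$members]), w64)
    expect_equal(oc2$score, oc$score)
    expect_equal(oc2$eta, oc$eta)
    expect_equal(oc2$density, oc$density)
  }
})
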