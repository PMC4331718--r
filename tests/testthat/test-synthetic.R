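test_that("the generator is deterministic in its seed", {
  spec <- synthetic_spec(n_complexes = 4, p_background = 0.02,
                         n_background_vertices = 25, seed = 99)
  a <- generate_network(spec)
  b <- generate_network(spec)
  expect_identical(a$edges, b$edges)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$complexes, b$complexes)
  expect_equal(a$network, b$network)

  ## byte-identical serialization
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_edge_list(a$edges, f1); write_edge_list(b$edges, f2)
  expect_identical(readLines(f1), readLines(f2))

  c <- generate_network(synthetic_spec(n_complexes = 4, p_background = 0.02,
                                       n_background_vertices = 25, seed = 100))
  expect_false(identical(a$edges, c$edges))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1); x1 <- stats::runif(1)
  set.seed(1); invisible(generate_network(synthetic_spec(seed = 5)))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("at zero noise the planted complexes are exactly the cliques", {
  syn <- generate_network(synthetic_spec(n_complexes = 2, size_range = c(4, 4),
                                         p_within = 1, p_background = 0,
                                         n_background_vertices = 0, seed = 2))
  sort_cx <- function(x) x[order(vapply(x, paste, character(1),
                                        collapse = " "))]
  expect_equal(sort_cx(enumerate_maximal_cliques(syn$network)),
               sort_cx(syn$complexes))
  ## ... and the candidate cliques coincide with ground truth
  cands <- generate_candidates(syn$network, w55)
  expect_equal(sort_cx(lapply(cands, `[[`, "members")), sort_cx(syn$complexes))
})

test_that("spec validation rejects degenerate settings", {
  expect_error(synthetic_spec(size_range = c(2, 4)))
  expect_error(synthetic_spec(p_background = 1.5))
  expect_error(synthetic_spec(n_complexes = 0))
  expect_error(synthetic_spec(retention = c(T1 = 0.5, T2 = 0.5),
                              background_retention = c(T1 = 0.5, TX = 0.5)))
})

test_that("add_random_edges adds exactly n typed edges, non-destructively", {
  syn <- generate_network(synthetic_spec(n_complexes = 3, p_background = 0,
                                         n_background_vertices = 5, seed = 4))
  net <- syn$network
  n0 <- nrow(net$edges)
  expect_identical(add_random_edges(net, 0), net)
  more <- add_random_edges(net, 10, seed = 1)
  expect_equal(nrow(more$edges), n0 + 10L)
  expect_equal(nrow(net$edges), n0)             # original untouched
  expect_equal(more$vertex_attrs, net$vertex_attrs)
  new_keys <- setdiff(names(more$edge_index), names(net$edge_index))
  expect_equal(length(new_keys), 10L)
  for (k in new_keys) {
    expect_equal(more$edge_types[[more$edge_index[[k]]]], "T1")
  }
  expect_identical(add_random_edges(net, 10, seed = 1)$edges, more$edges)
  max_new <- choose(length(net$vertices), 2) - n0
  expect_error(add_random_edges(net, max_new + 1), "absent pairs")
})

test_that("random edge injection degrades mean pipeline F-score", {
  base <- generate_network(synthetic_spec(n_complexes = 6, size_range = c(4, 5),
                                          p_background = 0.01,
                                          n_background_vertices = 30,
                                          p_background_annotated = 1,
                                          seed = 21))
  mean_f <- function(n_extra) {
    fs <- vapply(1:5, function(s) {
      net <- add_random_edges(base$network, n_extra, seed = s)
      recs <- data.frame(
        protein_a = rep(net$edges$a, lengths(net$edge_types)),
        protein_b = rep(net$edges$b, lengths(net$edge_types)),
        source_type = unlist(net$edge_types))
      ann <- base$annotations[base$annotations$protein %in% net$vertices, ]
      fit <- suppressMessages(
        predict_complexes(recs, ann, weight_mode = "equal",
                          extend_thres = 0.1))
      if (length(fit$complexes) == 0L) return(0)
      suppressMessages(
        match_and_score(fit, base$complexes))$f_score
    }, numeric(1))
    mean(fs)
  }
  f0 <- mean_f(0)
  f_hi <- mean_f(120)
  expect_gte(f0, f_hi)
})

test_that("the worked-example fixture reproduces every printed statistic", {
  net <- worked_example_network()
  expect_equal(length(net$vertices), 8L)
  expect_true(all(vapply(net$vertex_attrs, function(a) "GS1" %in% a,
                         logical(1))))
  expect_setequal(names(Filter(function(a) "GS2" %in% a, net$vertex_attrs)),
                  c("P2", "P3", "P4", "P5"))
  ## frozen regression: the full printed table at 3 decimals
  tab <- data.frame(
    clique = I(list(c("P2", "P5", "P6"), c("P2", "P3", "P5"),
                    c("P2", "P3", "P4", "P5"))),
    S = I(list("GS1", c("GS1", "GS2"), c("GS1", "GS2"))),
    density = c(0.667, 0.867, 0.833),
    eta = c(0.625, 1, 1),
    score = c(1.251, 5.202, 6.664))
  for (i in seq_len(nrow(tab))) {
    oc <- clique_score(net, tab$clique[[i]], w64, digits = 3)
    expect_equal(oc$S, tab$S[[i]])
    expect_equal(oc$density, tab$density[i])
    expect_equal(oc$eta, tab$eta[i])
    expect_equal(round(oc$score, 3), tab$score[i])
  }
})
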