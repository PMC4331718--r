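## triangle A,B,C (all GS1+GS2, edges typed T1+T2) with satellites:
## D shares both terms and connects to all three members with dual-type
## edges; E is unannotated with a single T1 edge
closeness_net <- function() {
  pairs <- c("A B", "A C", "B C", "D A", "D B", "D C")
  m <- do.call(rbind, strsplit(pairs, " "))
  edges <- rbind(
    data.frame(protein_a = m[, 1], protein_b = m[, 2], source_type = "T1"),
    data.frame(protein_a = m[, 1], protein_b = m[, 2], source_type = "T2"),
    data.frame(protein_a = "E", protein_b = "A", source_type = "T1"))
  suppressMessages(build_network(
    edges, ann("A", "GS1 GS2", "B", "GS1 GS2", "C", "GS1 GS2",
               "D", "GS1 GS2")))
}

test_that("closeness multiplies annotation similarity by connectivity", {
  net <- closeness_net()
  seed <- clique_score(net, c("A", "B", "C"), w64)
  ## full similarity (2/3) x full connectivity (3/3)
  expect_equal(closeness_score(net, "D", seed, w64), 2 / 3)
  ## no shared annotation forces zero, however well-connected
  expect_equal(closeness_score(net, "E", seed, w64), 0)

  ## partial case: one shared term, one single-source edge into a 3-seed
  net2 <- net_from_pairs(c("A B", "A C", "B C", "F A"), type = "T1",
                         type_tags = c("T1", "T2"),
                         annotations = ann("A", "GS1 GS2", "B", "GS1 GS2",
                                           "C", "GS1 GS2", "F", "GS1"))
  seed2 <- clique_score(net2, c("A", "B", "C"), w64)
  expect_equal(closeness_score(net2, "F", seed2, w64), (1 / 3) * (0.6 / 3))

  expect_error(closeness_score(net, "A", seed, w64), "already in the seed")
  net3 <- net_from_pairs(c("A B", "A C", "B C", "X Y"),
                         annotations = ann("A", "GS1", "B", "GS1", "C", "GS1"))
  seed3 <- clique_score(net3, c("A", "B", "C"), w55)
  expect_error(closeness_score(net3, "X", seed3, w55), "no edge")
})

test_that("closeness is bounded by the similarity ceiling", {
  set.seed(404)
  n_checked <- 0L
  for (rep in 1:10) {
    edges <- random_typed_edges(10, 0.4)
    if (is.null(edges)) next
    vs <- unique(c(edges$protein_a, edges$protein_b))
    anns <- rbind(data.frame(protein = vs, go_slim = "GS0"),
                  random_annotations(vs))
    net <- suppressMessages(build_network(edges, anns))
    cands <- generate_candidates(net, w64)
    for (seed in cands) {
      nbs <- setdiff(net$vertices, seed$members)
      for (v in nbs) {
        sc <- tryCatch(closeness_score(net, v, seed, w64),
                       error = function(e) NULL)
        if (is.null(sc)) next
        n_checked <- n_checked + 1L
        expect_gte(sc, 0)
        expect_lt(sc, length(seed$S) / (length(seed$S) + 1))
      }
    }
  }
  expect_gt(n_checked, 0L)
})

test_that("attachment sets shrink monotonically in extend_thres", {
  for (s in c(3, 8)) {
    syn <- generate_network(synthetic_spec(n_complexes = 5, p_background = 0.03,
                                           n_background_vertices = 40,
                                           p_background_annotated = 0.9,
                                           seed = s))
    net <- syn$network
    seeds <- select_seeds(net, generate_candidates(net, w55), w55)
    lo <- augment_seeds(net, seeds, w55, extend_thres = 0.1)
    hi <- augment_seeds(net, seeds, w55, extend_thres = 0.6)
    lo_att <- lapply(lo, function(x) names(x$attachments))
    hi_att <- lapply(hi, function(x) names(x$attachments))
    ## complexes may deduplicate differently; compare per seed
    lo_by_seed <- stats::setNames(lo_att, vapply(lo, function(x)
      paste(x$seed$members, collapse = ","), character(1)))
    hi_by_seed <- stats::setNames(hi_att, vapply(hi, function(x)
      paste(x$seed$members, collapse = ","), character(1)))
    for (k in names(hi_by_seed)) {
      expect_true(all(hi_by_seed[[k]] %in% lo_by_seed[[k]]))
    }
  }
})

test_that("threshold 0 attaches every seed-adjacent vertex", {
  net <- closeness_net()
  seeds <- select_seeds(net, generate_candidates(net, w64), w64)
  cx <- augment_seeds(net, seeds, w64, extend_thres = 0)
  ## seed is the 4-clique A-D; E is adjacent and attaches at threshold 0
  expect_equal(cx[[1L]]$members, c("A", "B", "C", "D", "E"))
  expect_true(all(cx[[1L]]$seed$members %in% cx[[1L]]$members))
  expect_error(augment_seeds(net, seeds, w64, extend_thres = 1.5))
})

test_that("every predicted complex contains its full seed clique", {
  syn <- generate_network(synthetic_spec(n_complexes = 6, p_background = 0.02,
                                         n_background_vertices = 30, seed = 12))
  fit <- suppressMessages(predict_complexes(syn$edges, syn$annotations))
  for (cx in fit$complexes) {
    expect_true(all(cx$seed$members %in% cx$members))
    expect_equal(length(intersect(names(cx$attachments), cx$seed$members)), 0L)
  }
})

test_that("duplicate member sets are deduplicated", {
  net <- closeness_net()
  seed <- clique_score(net, c("A", "B", "C"), w64)
  cx <- augment_seeds(net, list(seed, seed), w64, extend_thres = 0.1)
  expect_equal(length(cx), 1L)
})
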