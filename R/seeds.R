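#' Reduce ranked candidate cliques to a disjoint seed set
#'
#' Candidate maximal ontology-correlated cliques generally overlap; seeds
#' must not.  The default `"prune"` rule walks the ranking: the top candidate
#' becomes a seed, its vertices are deleted from every remaining candidate,
#' candidates falling below `min_size` vertices are dropped, the pruned
#' survivors (a subset of a clique is still a clique) are re-scored with
#' their new common annotation set and re-ranked, and the walk repeats until
#' no candidate remains.  The `"discard"` alternative instead drops any
#' candidate whose fractional overlap with an accepted seed reaches
#' `overlap_threshold` (remaining candidates still have seeded vertices
#' subtracted so the output stays disjoint).
#'
#' @param network The `attributed_network` the candidates came from.
#' @param candidates Ranked list of `onto_clique` objects (from
#'   [generate_candidates()]).
#' @param weights The [source_weights()] used for scoring.
#' @param method `"prune"` (default) or `"discard"`.
#' @param overlap_threshold Overlap fraction |C ∩ seed| / |C| at or above
#'   which `"discard"` drops a candidate (default 0.5).
#' @param min_size Minimum surviving clique size (default 3).
#' @return A list of pairwise vertex-disjoint `onto_clique` objects in
#'   descending score order, with class `seed_set`.
#' @export
select_seeds <- function(network, candidates, weights,
                         method = c("prune", "discard"),
                         overlap_threshold = 0.5, min_size = 3L) {
  stopifnot(inherits(network, "attributed_network"))
  method <- match.arg(method)
  eta_fn <- make_eta_cache(network)
  pool <- rank_onto_cliques(candidates)
  seeds <- list()
  seeded <- character()
  while (length(pool)) {
    top <- pool[[1L]]
    seeds[[length(seeds) + 1L]] <- top
    seeded <- c(seeded, top$members)
    pool <- pool[-1L]
    if (!length(pool)) break
    kept <- list()
    for (cand in pool) {
      if (method == "discard") {
        ov <- length(intersect(cand$members, top$members)) / length(cand$members)
        if (ov >= overlap_threshold) next
      }
      rest <- setdiff(cand$members, seeded)
      if (length(rest) < min_size) next
      if (length(rest) == length(cand$members)) {
        kept[[length(kept) + 1L]] <- cand
      } else {
        pruned <- score_clique_internal(network, rest, weights, eta_fn)
        if (pruned$score > 0) kept[[length(kept) + 1L]] <- pruned
      }
    }
    pool <- rank_onto_cliques(kept)
  }
  ## disjointness is an invariant, not an expectation: fail loudly if broken
  all_members <- unlist(lapply(seeds, `[[`, "members"), use.names = FALSE)
  stopifnot(!anyDuplicated(all_members))
  structure(seeds, class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("Seed clique set:", length(x), "disjoint seed(s)\n")
  for (i in seq_along(x)) {
    s <- x[[i]]
    cat(sprintf("  [%d] {%s}  |S|=%d  score=%.3f\n", i,
                paste(s$members, collapse = ", "), length(s$S), s$score))
  }
  invisible(x)
}
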