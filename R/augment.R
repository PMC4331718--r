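#' Closeness of a neighbor protein to a seed clique
#'
#' The closeness score of a vertex P_k with annotation set S_k to a seed
#' clique (C_j, S_j) is the product of an annotation-similarity term,
#' |S_k ∩ S_j| / (|S_j| + 1), and a weighted-connectivity term, the summed
#' source weights of the edges between P_k and C_j divided by |C_j|.  Both
#' terms lie in \[0, 1), so a high score needs shared annotations *and*
#' strong, well-supported connectivity; a vertex sharing no annotation with
#' the seed scores 0.
#'
#' @param network An `attributed_network`.
#' @param vertex A vertex ID outside the seed with at least one edge into
#'   the seed.
#' @param seed An `onto_clique` (fields `members` and `S` are used).
#' @param weights A [source_weights()] vector.
#' @return A scalar in \[0, |S_j|/(|S_j|+1)).
#' @export
closeness_score <- function(network, vertex, seed, weights) {
  stopifnot(inherits(network, "attributed_network"),
            is.character(vertex), length(vertex) == 1L,
            inherits(seed, "onto_clique"))
  if (vertex %in% seed$members) stop("vertex is already in the seed clique")
  if (!vertex %in% network$vertices) stop("vertex not in network: ", vertex)
  keys <- edge_key(vertex, seed$members)
  idx <- network$edge_index[keys]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) stop("vertex has no edge into the seed clique")
  sim <- length(intersect(network$vertex_attrs[[vertex]], seed$S)) /
    (length(seed$S) + 1)
  conn <- edge_weight_sum(network, unname(idx), weights) / length(seed$members)
  sim * conn
}

#' Grow seed cliques into predicted complexes
#'
#' Every network vertex adjacent to a seed is scored with
#' [closeness_score()] against the fixed seed (the seed's member set and
#' annotation set do not change while its neighbors are scored, so the
#' attachment set shrinks monotonically as `extend_thres` grows).  All
#' neighbors scoring at least `extend_thres` are attached.  Seeds are grown
#' independently, so final complexes may overlap even though seeds are
#' disjoint; predictions with identical member sets are deduplicated
#' (first in seed order kept).
#'
#' @param network An `attributed_network`.
#' @param seeds A `seed_set` (or list of `onto_clique`s).
#' @param weights A [source_weights()] vector.
#' @param extend_thres Attachment threshold in \[0, 1\] (default 0.1).
#' @return A list of `predicted_complex` objects: `seed`, `attachments`
#'   (named closeness scores), `members`.
#' @export
augment_seeds <- function(network, seeds, weights, extend_thres = 0.1) {
  stopifnot(inherits(network, "attributed_network"),
            is.numeric(extend_thres), length(extend_thres) == 1L,
            extend_thres >= 0, extend_thres <= 1)
  nb <- adjacency_list(network)
  out <- list()
  seen <- character()
  for (seed in seeds) {
    cand <- setdiff(sort(unique(unlist(nb[seed$members], use.names = FALSE))),
                    seed$members)
    scores <- vapply(cand, function(v)
      closeness_score(network, v, seed, weights), numeric(1))
    att <- scores[scores >= extend_thres]
    members <- sort(c(seed$members, names(att)), method = "radix")
    key <- paste(members, collapse = "\t")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- structure(
      list(seed = seed, attachments = att, members = members),
      class = "predicted_complex")
  }
  out
}

#' @export
print.predicted_complex <- function(x, ...) {
  cat("Predicted complex (", length(x$members), " members)\n", sep = "")
  cat("  seed: {", paste(x$seed$members, collapse = ", "), "}  score ",
      sprintf("%.3f", x$seed$score), "\n", sep = "")
  if (length(x$attachments)) {
    cat("  attachments:",
        paste(sprintf("%s (%.3f)", names(x$attachments), x$attachments),
              collapse = ", "), "\n")
  } else {
    cat("  attachments: none\n")
  }
  invisible(x)
}
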