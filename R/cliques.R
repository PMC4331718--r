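#' Enumerate maximal cliques
#'
#' All maximal cliques of the plain (unattributed) graph with at least
#' `min_size` vertices, via igraph's pivoted Bron-Kerbosch enumeration.
#' Output order is deterministic: size descending, then lexicographic member
#' tuple.
#'
#' @param network An `attributed_network`.
#' @param min_size Minimum clique size (default 3, the smallest clique that
#'   can witness structural correlation).
#' @return A list of character vectors (sorted members).
#' @export
enumerate_maximal_cliques <- function(network, min_size = 3L) {
  stopifnot(inherits(network, "attributed_network"), min_size >= 2L)
  if (nrow(network$edges) == 0L) return(list())
  g <- as_igraph(network)
  mc <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(mc, function(x) sort(names(x), method = "radix"))
  order_cliques(cl)
}

## Deterministic clique ordering: size desc, then member tuple lexicographic.
order_cliques <- function(cl) {
  if (length(cl) == 0L) return(cl)
  key <- vapply(cl, paste, character(1), collapse = "\t")
  cl[order(-lengths(cl), key, method = "radix")]
}

#' Common annotation attribute set of a vertex set
#'
#' The intersection of the GO-slim attribute sets of all vertices; empty as
#' soon as one member is unannotated.
#'
#' @param network An `attributed_network`.
#' @param clique Character vector of vertex IDs (must be in the network).
#' @return Sorted character vector of shared terms (possibly empty).
#' @export
common_attribute_set <- function(network, clique) {
  stopifnot(inherits(network, "attributed_network"))
  if (length(clique) == 0L) stop("empty vertex set has no common attribute set")
  if (!all(clique %in% network$vertices)) {
    stop("vertex set contains IDs not in the network")
  }
  sort(Reduce(intersect, network$vertex_attrs[clique]))
}

#' Structural correlation eta(S) of an annotation set
#'
#' The fraction of vertices of the S-induced subgraph G(S) that belong to at
#' least one clique of size >= 3 within G(S) (equivalently, that lie on a
#' triangle of G(S)).  eta is 1 when every S-annotated protein sits in a
#' dense S-annotated neighborhood and 0 when none does; it measures how
#' predictive the annotation set is of cohesive structure.  Returns 0 when
#' V(S) is empty.
#'
#' @param network An `attributed_network`.
#' @param S Character vector of GO-slim terms (the empty set induces the
#'   whole network, so eta(empty) is the overall triangle-vertex fraction).
#' @return A scalar in \[0, 1\].
#' @export
structural_correlation <- function(network, S) {
  sub <- induced_subgraph(network, S)
  nV <- length(sub$vertices)
  if (nV == 0L) return(0)
  if (nrow(sub$edges) == 0L) return(0)
  tri <- igraph::count_triangles(as_igraph(sub))
  sum(tri > 0L) / nV
}

#' Source-weighted density of a vertex set
#'
#' Twice the sum of the [edge_weight()]s of the internal edges of `C`,
#' divided by |C| (|C| - 1).  For a clique whose edges all carry every source
#' type the density is 1 under any normalized weights.
#'
#' @param network An `attributed_network`.
#' @param C Character vector of at least two vertex IDs.
#' @param weights A [source_weights()] vector.
#' @return A non-negative scalar (at most 1 for normalized weights).
#' @export
attributed_density <- function(network, C, weights) {
  stopifnot(inherits(network, "attributed_network"))
  n <- length(C)
  if (n < 2L) stop("density needs at least 2 vertices")
  idx <- internal_edge_idx(network, C)
  2 * edge_weight_sum(network, idx, weights) / (n * (n - 1))
}

## Is C a clique of the network?
is_clique <- function(network, C) {
  n <- length(C)
  if (n < 2L) return(n == 1L)
  length(internal_edge_idx(network, C)) == n * (n - 1) / 2
}

## Memoized eta: returns a function(S) caching by the sorted term tuple.
make_eta_cache <- function(network) {
  cache <- new.env(parent = emptyenv())
  function(S) {
    key <- paste0("S:", paste(sort(S), collapse = "\t"))
    if (is.null(cache[[key]])) {
      cache[[key]] <- structural_correlation(network, S)
    }
    cache[[key]]
  }
}

## Shared scoring core.  eta_fn allows memoization across many cliques.
score_clique_internal <- function(network, members, weights, eta_fn,
                                  digits = NULL) {
  members <- sort(members, method = "radix")
  n <- length(members)
  S <- common_attribute_set(network, members)
  density <- attributed_density(network, members, weights)
  eta <- if (length(S)) eta_fn(S) else eta_fn(character())
  if (!is.null(digits)) {
    eta <- round(eta, digits)
    density <- round(density, digits)
  }
  score <- eta * n * length(S) * density
  structure(list(
    members = members,
    S = S,
    eta = eta,
    density = density,
    score = score,
    n_edges = n * (n - 1) / 2
  ), class = "onto_clique")
}

#' Score an ontology-correlated clique
#'
#' Computes the clique's common annotation set S, its structural correlation
#' eta(S), its source-weighted density, and the ontology-correlated clique
#' score eta(S) x |C| x |S| x Density(C).  A clique with no shared
#' annotation scores 0.
#'
#' @param network An `attributed_network`.
#' @param clique Character vector forming a clique of size >= 3.
#' @param weights A [source_weights()] vector.
#' @param digits Optional integer: round eta and density to this many
#'   decimals before composing the score.  This is the reporting convention
#'   of the worked examples (scores recomposed from 3-decimal tables);
#'   `NULL` (default) keeps full precision.
#' @return An object of class `onto_clique` with fields `members`, `S`,
#'   `eta`, `density`, `score`, `n_edges`.
#' @examples
#' net <- worked_example_network()
#' w <- source_weights(c(T1 = 0.6, T2 = 0.4))
#' clique_score(net, c("P2", "P3", "P4", "P5"), w, digits = 3)
#' @export
clique_score <- function(network, clique, weights, digits = NULL) {
  stopifnot(inherits(network, "attributed_network"))
  if (length(clique) < 3L) stop("ontology-correlated cliques have >= 3 members")
  if (!all(clique %in% network$vertices)) {
    stop("clique contains IDs not in the network")
  }
  if (!is_clique(network, clique)) stop("input vertex set is not a clique")
  score_clique_internal(network, clique, weights, make_eta_cache(network),
                        digits = digits)
}

#' @export
print.onto_clique <- function(x, ...) {
  cat("Ontology-correlated clique {", paste(x$members, collapse = ", "),
      "}\n", sep = "")
  cat("  S = {", paste(x$S, collapse = ", "), "}\n", sep = "")
  cat(sprintf("  eta = %.3f  density = %.3f  score = %.3f\n",
              x$eta, x$density, x$score))
  invisible(x)
}

#' Generate candidate ontology-correlated cliques
#'
#' All maximal cliques of size >= `min_size` whose common annotation set is
#' non-empty, scored and ranked (score descending; ties broken by size
#' descending, then lexicographic member tuple — fully deterministic).
#' eta values are memoized per distinct common annotation set.
#'
#' @inheritParams clique_score
#' @param min_size Minimum clique size (default 3).
#' @return A list of `onto_clique` objects in rank order.
#' @export
generate_candidates <- function(network, weights, min_size = 3L) {
  cliques <- enumerate_maximal_cliques(network, min_size = min_size)
  eta_fn <- make_eta_cache(network)
  out <- vector("list", length(cliques))
  n_out <- 0L
  for (cl in cliques) {
    S <- common_attribute_set(network, cl)
    if (length(S) == 0L) next
    n_out <- n_out + 1L
    out[[n_out]] <- score_clique_internal(network, cl, weights, eta_fn)
  }
  rank_onto_cliques(out[seq_len(n_out)])
}

## Deterministic rank: score desc, size desc, lexicographic member tuple asc.
rank_onto_cliques <- function(cliques) {
  if (length(cliques) == 0L) return(cliques)
  score <- vapply(cliques, `[[`, numeric(1), "score")
  size <- vapply(cliques, function(x) length(x$members), integer(1))
  key <- vapply(cliques, function(x) paste(x$members, collapse = "\t"),
                character(1))
  cliques[order(-score, -size, key, method = "radix")]
}
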