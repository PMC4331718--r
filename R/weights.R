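#' Contribution degree of one PPI source
#'
#' The quality of the seed-clique set a source supports, per edge of that
#' source: sum over seeds of (clique score x number of internal clique
#' edges), divided by the total number of edges in the source dataset.
#'
#' @param seeds List of `onto_clique` seeds mined from the single-source
#'   network (a `seed_set` works).
#' @param total_type_edges Total number of edges in that source dataset
#'   (>= 1).
#' @return A non-negative scalar.
#' @export
c_degree <- function(seeds, total_type_edges) {
  stopifnot(is.numeric(total_type_edges), length(total_type_edges) == 1L,
            total_type_edges >= 1)
  if (length(seeds) == 0L) return(0)
  sc <- vapply(seeds, `[[`, numeric(1), "score")
  ne <- vapply(seeds, `[[`, numeric(1), "n_edges")
  sum(sc * ne) / total_type_edges
}

#' Estimate per-source contribution weights (phase 1)
#'
#' For each evidence source, builds the single-source attributed network,
#' mines and selects seed cliques at equal initial weights, and computes the
#' source's contribution degree.  Weights are the contribution degrees
#' normalized to sum to 1; if every contribution degree is 0 (no scoring
#' seeds anywhere) the weights fall back to equal.
#'
#' @param edges_by_type Named list of typed edge data frames, one per source
#'   tag (names are the tags; each data frame as from [read_edge_list()]).
#' @param annotations Optional annotation data frame.
#' @param min_size Minimum clique size (default 3).
#' @param seed_method Passed to [select_seeds()].
#' @return An object of class `contribution_report`: a per-source table of
#'   edge counts, contribution degrees and weights, plus the resulting
#'   [source_weights()].
#' @examples
#' syn <- generate_network(synthetic_spec(n_complexes = 3, seed = 1))
#' by_type <- split(syn$edges, syn$edges$source_type)
#' compute_source_weights(by_type, syn$annotations)
#' @export
compute_source_weights <- function(edges_by_type, annotations = NULL,
                                   min_size = 3L, seed_method = "prune") {
  stopifnot(is.list(edges_by_type), length(edges_by_type) >= 1L)
  tags <- names(edges_by_type)
  if (is.null(tags) || !all(nzchar(tags)) || anyDuplicated(tags)) {
    stop("'edges_by_type' must be a named list with unique source tags")
  }
  n_edges <- vapply(edges_by_type, nrow, integer(1))
  if (all(n_edges == 0L)) stop("all sources are empty")
  init_w <- source_weights(stats::setNames(rep(1, length(tags)), tags))
  cd <- stats::setNames(numeric(length(tags)), tags)
  for (tag in tags) {
    ed <- edges_by_type[[tag]]
    if (nrow(ed) == 0L) next
    ed$source_type <- tag
    net <- build_network(ed, annotations, type_tags = tags)
    cands <- generate_candidates(net, init_w, min_size = min_size)
    seeds <- select_seeds(net, cands, init_w, method = seed_method,
                          min_size = min_size)
    cd[[tag]] <- c_degree(seeds, nrow(ed))
  }
  w <- if (sum(cd) > 0) cd / sum(cd) else
    stats::setNames(rep(1 / length(tags), length(tags)), tags)
  structure(list(
    table = data.frame(type = tags, n_edges = n_edges, c_degree = unname(cd),
                       weight = unname(w), stringsAsFactors = FALSE,
                       row.names = NULL),
    weights = source_weights(w)
  ), class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("Per-source contribution report\n")
  tab <- x$table
  tab$c_degree <- round(tab$c_degree, 4)
  tab$weight <- round(tab$weight, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
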