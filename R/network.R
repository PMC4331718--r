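## Canonical unordered-pair key. IDs never contain whitespace (they come from
## whitespace-split input), so a tab separator is unambiguous.
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")

## Internal constructor: assumes edges already canonicalized (a < b), one row
## per pair, edge_types parallel to rows, vertex_attrs covering all vertices.
new_attributed_network <- function(vertices, edges, edge_types, vertex_attrs,
                                   type_tags) {
  ord <- order(edges$a, edges$b, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  edge_types <- edge_types[ord]
  rownames(edges) <- NULL
  keys <- if (nrow(edges)) edge_key(edges$a, edges$b) else character()
  index <- stats::setNames(seq_len(nrow(edges)), keys)
  vertices <- sort(vertices, method = "radix")
  vertex_attrs <- vertex_attrs[vertices]
  structure(list(
    vertices = vertices,
    edges = edges,
    edge_types = edge_types,
    edge_index = index,
    vertex_attrs = vertex_attrs,
    attr_terms = sort(unique(unlist(vertex_attrs, use.names = FALSE))),
    type_tags = type_tags
  ), class = "attributed_network")
}

#' Build an attributed PPI network
#'
#' Assembles the 6-tuple network G = (V, E, A_v, A_e, F_v, F_e): protein
#' vertices with GO-slim attribute sets and undirected edges with non-empty
#' evidence-source type sets.  Vertices are exactly the proteins that occur
#' in `edges`; an edge reported under several source types carries the union
#' of the types.  Proteins without annotations are retained with an empty
#' attribute set; annotations for proteins absent from the edge set are
#' ignored (with a message).
#'
#' @param edges Data frame of typed edge records (columns `protein_a`,
#'   `protein_b`, `source_type`), e.g. from [read_edge_list()]; rows from
#'   several sources can be `rbind`ed together.
#' @param annotations Optional data frame with columns `protein`, `go_slim`
#'   (see [read_annotations()]).
#' @param type_tags Optional character vector declaring the full set of
#'   source tags A_e (defaults to the tags present in `edges`).  Declaring
#'   tags explicitly matters when a single-source network is carved out of a
#'   multi-source study.
#' @return An object of class `attributed_network`.
#' @examples
#' edges <- data.frame(protein_a = c("A", "A", "B"),
#'                     protein_b = c("B", "B", "C"),
#'                     source_type = c("T1", "T2", "T1"))
#' ann <- data.frame(protein = c("A", "B"), go_slim = c("GS1", "GS1"))
#' net <- build_network(edges, ann)
#' edge_weight(net, c("A", "B"), source_weights(c(T1 = 0.6, T2 = 0.4)))
#' @export
build_network <- function(edges, annotations = NULL, type_tags = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b", "source_type") %in% names(edges)))
  if (nrow(edges) == 0L) stop("cannot build a network from zero edges")
  a <- as.character(edges$protein_a)
  b <- as.character(edges$protein_b)
  ty <- as.character(edges$source_type)
  if (anyNA(a) || anyNA(b) || anyNA(ty) ||
      !all(nzchar(a)) || !all(nzchar(b)) || !all(nzchar(ty))) {
    stop("edge records must have non-empty protein IDs and source types")
  }
  if (any(a == b)) stop("edge records contain self-loops; drop them first")
  keys <- edge_key(a, b)
  by_key <- split(ty, keys)
  uk <- names(by_key)
  parts <- strsplit(uk, "\t", fixed = TRUE)
  edf <- data.frame(a = vapply(parts, `[[`, character(1), 1L),
                    b = vapply(parts, `[[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  edge_types <- lapply(by_key, function(x) sort(unique(x)))
  tags <- sort(unique(ty))
  if (!is.null(type_tags)) {
    if (!all(tags %in% type_tags)) {
      stop("edges carry source types not in 'type_tags'")
    }
    tags <- sort(unique(as.character(type_tags)))
  }
  vertices <- sort(unique(c(edf$a, edf$b)))
  vattrs <- stats::setNames(rep(list(character()), length(vertices)), vertices)
  if (!is.null(annotations) && nrow(annotations)) {
    stopifnot(all(c("protein", "go_slim") %in% names(annotations)))
    p <- as.character(annotations$protein)
    g <- as.character(annotations$go_slim)
    known <- p %in% vertices
    if (any(!known)) {
      message("build_network: ignored ", sum(!known),
              " annotation(s) for proteins absent from the edge set")
    }
    if (any(known)) {
      ann <- lapply(split(g[known], p[known]), function(x) sort(unique(x)))
      vattrs[names(ann)] <- ann
    }
  }
  new_attributed_network(vertices, edf, unname(edge_types), vattrs, tags)
}

#' Per-source contribution weights
#'
#' A named weight vector over the evidence-source type tags, normalized to
#' sum to one.  Edge weights are sums of the weights of the types
#' an edge carries, so an edge confirmed by every source weighs 1.
#'
#' @param w Named non-negative numeric vector (names are type tags).  It is
#'   normalized to sum to 1.
#' @return Object of class `source_weights` (a named numeric vector).
#' @examples
#' source_weights(c(T1 = 0.6, T2 = 0.4))
#' @export
source_weights <- function(w) {
  stopifnot(is.numeric(w), length(w) >= 1L)
  if (is.null(names(w)) || anyNA(names(w)) || !all(nzchar(names(w))) ||
      anyDuplicated(names(w))) {
    stop("'w' must have unique non-empty names (the source type tags)")
  }
  if (anyNA(w) || any(w < 0)) stop("weights must be non-negative")
  s <- sum(w)
  if (s <= 0) stop("at least one weight must be positive")
  structure(w / s, class = "source_weights")
}

#' @export
print.source_weights <- function(x, ...) {
  cat("Source contribution weights:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Weight of an edge under source contribution weights
#'
#' The weight of an edge is the sum of the contribution weights of the
#' source types it carries: an edge seen by every source weighs 1, an edge
#' seen only by source i weighs w_i.
#'
#' @param network An `attributed_network`.
#' @param edge Character vector of the two endpoint IDs (order irrelevant).
#' @param weights A [source_weights()] vector covering the edge's types.
#' @return A scalar in (0, 1].
#' @export
edge_weight <- function(network, edge, weights) {
  stopifnot(inherits(network, "attributed_network"),
            is.character(edge), length(edge) == 2L)
  idx <- unname(network$edge_index[edge_key(edge[1L], edge[2L])])
  if (is.na(idx)) stop("edge not in network: ", edge[1L], " -- ", edge[2L])
  types <- network$edge_types[[idx]]
  if (!all(types %in% names(weights))) {
    stop("weights do not cover source type(s): ",
         paste(setdiff(types, names(weights)), collapse = ", "))
  }
  sum(unclass(weights)[types])
}

## Row indices of edges with both endpoints in vertex set C.
internal_edge_idx <- function(network, C) {
  which(network$edges$a %in% C & network$edges$b %in% C)
}

## Sum of source-weighted edge weights over given edge rows.
edge_weight_sum <- function(network, idx, weights) {
  w <- unclass(weights)
  if (length(idx) == 0L) return(0)
  sum(vapply(network$edge_types[idx], function(t) sum(w[t]), numeric(1)))
}

#' Attribute-induced subgraph G(S)
#'
#' The subgraph induced by an annotation set S keeps exactly the vertices
#' whose attribute set contains every term of S (isolated vertices
#' included), and the edges with both endpoints kept.  The empty S induces
#' the whole network; a term carried by no vertex induces the empty network.
#'
#' @param network An `attributed_network`.
#' @param S Character vector of GO-slim terms.
#' @return An `attributed_network` restricted to V(S).
#' @export
induced_subgraph <- function(network, S) {
  stopifnot(inherits(network, "attributed_network"), is.character(S) || length(S) == 0L)
  S <- unique(as.character(S))
  if (length(S) == 0L) return(network)
  keep <- vapply(network$vertex_attrs, function(at) all(S %in% at), logical(1))
  vs <- network$vertices[keep]
  eidx <- internal_edge_idx(network, vs)
  new_attributed_network(
    vertices = vs,
    edges = network$edges[eidx, , drop = FALSE],
    edge_types = network$edge_types[eidx],
    vertex_attrs = network$vertex_attrs[vs],
    type_tags = network$type_tags
  )
}

#' Convert an attributed network to an igraph graph
#'
#' The plain (unattributed) undirected simple graph; used internally for
#' clique enumeration and triangle counting.
#'
#' @param network An `attributed_network`.
#' @return An `igraph` object with vertex names.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "attributed_network"))
  igraph::graph_from_data_frame(
    network$edges[, c("a", "b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = network$vertices, stringsAsFactors = FALSE)
  )
}

## Neighbor map: named list vertex -> character vector of neighbors.
adjacency_list <- function(network) {
  nb <- stats::setNames(rep(list(character()), length(network$vertices)),
                        network$vertices)
  if (nrow(network$edges)) {
    ea <- network$edges$a; eb <- network$edges$b
    for (nm in names(nb)) nb[[nm]] <- character()
    sp1 <- split(eb, ea)
    sp2 <- split(ea, eb)
    for (nm in names(sp1)) nb[[nm]] <- c(nb[[nm]], sp1[[nm]])
    for (nm in names(sp2)) nb[[nm]] <- c(nb[[nm]], sp2[[nm]])
    nb <- lapply(nb, function(x) sort(unique(x)))
  }
  nb
}

#' @export
print.attributed_network <- function(x, ...) {
  cat("Attributed PPI network\n")
  cat("  vertices: ", length(x$vertices),
      " (", sum(lengths(x$vertex_attrs) > 0), " annotated)\n", sep = "")
  cat("  edges:    ", nrow(x$edges), "\n", sep = "")
  cat("  source tags A_e: ", paste(x$type_tags, collapse = ", "), "\n", sep = "")
  cat("  annotation terms A_v: ", length(x$attr_terms), "\n", sep = "")
  invisible(x)
}

#' @export
summary.attributed_network <- function(object, ...) {
  tc <- table(vapply(object$edge_types, paste, character(1), collapse = "+"))
  out <- list(
    n_vertices = length(object$vertices),
    n_annotated = sum(lengths(object$vertex_attrs) > 0),
    n_edges = nrow(object$edges),
    n_terms = length(object$attr_terms),
    type_tags = object$type_tags,
    edges_by_type_set = tc
  )
  class(out) <- "summary.attributed_network"
  out
}

#' @export
print.summary.attributed_network <- function(x, ...) {
  cat("Attributed PPI network summary\n")
  cat("  vertices:", x$n_vertices, " annotated:", x$n_annotated, "\n")
  cat("  edges:   ", x$n_edges, " annotation terms:", x$n_terms, "\n")
  cat("  edges by source type set:\n")
  print(x$edges_by_type_set)
  invisible(x)
}
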