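## Independent brute-force oracles and small graph builders used across the
## suite.  The oracles enumerate vertex subsets directly and never touch the
## package's clique machinery.

adj_matrix <- function(net) {
  v <- net$vertices
  A <- matrix(FALSE, length(v), length(v), dimnames = list(v, v))
  if (nrow(net$edges)) {
    A[cbind(net$edges$a, net$edges$b)] <- TRUE
    A[cbind(net$edges$b, net$edges$a)] <- TRUE
  }
  A
}

## All maximal cliques of size >= min_size by exhaustive subset enumeration
## (feasible for <= 12 vertices), ordered like the package output.
brute_maximal_cliques <- function(net, min_size = 3L) {
  v <- net$vertices
  A <- adj_matrix(net)
  n <- length(v)
  out <- list()
  for (m in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) < min_size) next
    sub <- A[idx, idx, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) next
    outside <- setdiff(seq_len(n), idx)
    if (length(outside) &&
        any(vapply(outside, function(o) all(A[o, idx]), logical(1)))) next
    out[[length(out) + 1L]] <- v[idx]
  }
  key <- vapply(out, paste, character(1), collapse = "\t")
  out[order(-lengths(out), key, method = "radix")]
}

## Vertices lying in at least one clique of size >= 3 (equivalently, on a
## triangle), by exhaustive triple enumeration.
brute_triangle_vertices <- function(net) {
  v <- net$vertices
  A <- adj_matrix(net)
  n <- length(v)
  hit <- logical(n)
  if (n >= 3L) {
    for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
      if (A[i, j] && A[i, k] && A[j, k]) hit[c(i, j, k)] <- TRUE
    }
  }
  v[hit]
}

## Typed edge records for an Erdos-Renyi graph; each kept edge gets T1, T2 or
## both.  Caller seeds the RNG.  Returns NULL when no edge survives.
random_typed_edges <- function(n_vertices, p, p_both = 0.3) {
  v <- sprintf("V%02d", seq_len(n_vertices))
  pr <- utils::combn(v, 2L)
  keep <- which(stats::runif(ncol(pr)) < p)
  if (length(keep) == 0L) return(NULL)
  rows <- lapply(keep, function(k) {
    types <- if (stats::runif(1) < p_both) c("T1", "T2") else
      sample(c("T1", "T2"), 1L)
    data.frame(protein_a = pr[1L, k], protein_b = pr[2L, k],
               source_type = types, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Random annotations: each vertex gets 0..2 terms from a small vocabulary.
random_annotations <- function(vertices, terms = paste0("GS", 1:4)) {
  rows <- lapply(vertices, function(v) {
    k <- sample(0:2, 1L)
    if (k == 0L) return(NULL)
    data.frame(protein = v, go_slim = sample(terms, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(protein = character(), go_slim = character())
  else out
}

## Compact network builder: pairs like c("A B", "B C"), one type for all.
net_from_pairs <- function(pairs, type = "T1", annotations = NULL,
                           type_tags = NULL) {
  m <- do.call(rbind, strsplit(pairs, " ", fixed = TRUE))
  edges <- data.frame(protein_a = m[, 1L], protein_b = m[, 2L],
                      source_type = type, stringsAsFactors = FALSE)
  suppressMessages(build_network(edges, annotations, type_tags = type_tags))
}

## Annotation table builder: ann("A", "GS1", "B", "GS1 GS2").
ann <- function(...) {
  x <- list(...)
  stopifnot(length(x) %% 2 == 0)
  prot <- character(); term <- character()
  for (i in seq(1, length(x), by = 2)) {
    ts <- strsplit(x[[i + 1L]], " ", fixed = TRUE)[[1L]]
    prot <- c(prot, rep(x[[i]], length(ts)))
    term <- c(term, ts)
  }
  data.frame(protein = prot, go_slim = term, stringsAsFactors = FALSE)
}

w64 <- source_weights(c(T1 = 0.6, T2 = 0.4))
w55 <- source_weights(c(T1 = 0.5, T2 = 0.5))
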