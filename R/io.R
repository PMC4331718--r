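#' Read a typed PPI edge list
#'
#' Reads a whitespace/tab-separated edge list (two ID columns; extra columns
#' are ignored) and attaches one evidence-source type tag to every edge.
#' Lines starting with `#` and blank lines are skipped.  Pairs are
#' canonicalized as unordered (the lexicographically smaller ID first), so
#' `A B` and `B A` are the same edge; duplicates are collapsed and self-loops
#' are dropped with a message.
#'
#' @param path Path to the edge-list file.
#' @param source_type Single type tag to attach to every edge in this file
#'   (e.g. `"T1"` for high-throughput, `"T2"` for literature-extracted).
#' @return A data frame with columns `protein_a`, `protein_b`, `source_type`,
#'   one row per distinct unordered pair.
#' @seealso [build_network()], [read_annotations()]
#' @export
read_edge_list <- function(path, source_type) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  if (!is.character(source_type) || length(source_type) != 1L ||
      is.na(source_type) || !nzchar(source_type)) {
    stop("'source_type' must be a single non-empty type tag")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      source_type = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- lengths(fields) < 2L
  if (any(bad)) {
    stop("malformed edge-list line ", idx[which(bad)[1L]], " in ", path,
         ": fewer than 2 fields")
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  self <- a == b
  if (any(self)) {
    message("read_edge_list: dropped ", sum(self), " self-loop(s)")
    a <- a[!self]; b <- b[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\t"))
  data.frame(protein_a = lo[!dup], protein_b = hi[!dup],
             source_type = rep(source_type, sum(!dup)),
             stringsAsFactors = FALSE)
}

#' Write a (two-column) edge list
#'
#' Writes `protein_a<TAB>protein_b` lines; the source type is a property of
#' the file, supplied again at read time.
#'
#' @param edges Data frame with columns `protein_a` and `protein_b`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b") %in% names(edges)))
  writeLines(paste(edges$protein_a, edges$protein_b, sep = "\t"), path)
  invisible(path)
}

#' Read a protein-to-GO-slim annotation table
#'
#' Two tab/whitespace-separated columns: protein ID and GO-slim term ID.
#' Duplicate (protein, term) pairs collapse to one record; `#`-comment and
#' blank lines are skipped.  Term IDs are opaque labels (no ontology-graph
#' reasoning is done).
#'
#' @param path Path to the annotation file.
#' @return Data frame with columns `protein`, `go_slim`.
#' @export
read_annotations <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(protein = character(), go_slim = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- lengths(fields) < 2L
  if (any(bad)) {
    stop("malformed annotation line ", idx[which(bad)[1L]], " in ", path,
         ": fewer than 2 fields")
  }
  protein <- vapply(fields, `[[`, character(1), 1L)
  term <- vapply(fields, `[[`, character(1), 2L)
  dup <- duplicated(paste(protein, term, sep = "\t"))
  data.frame(protein = protein[!dup], go_slim = term[!dup],
             stringsAsFactors = FALSE)
}

#' Read annotations from a GAF 2.x file
#'
#' Convenience converter: takes the DB object ID (column 2) and GO ID
#' (column 5) from a Gene Association File.  `!`-comment lines are skipped.
#'
#' @param path Path to the GAF file.
#' @return Data frame with columns `protein`, `go_slim`.
#' @export
read_gaf_annotations <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(!|$)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(protein = character(), go_slim = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5L)) {
    stop("GAF line with fewer than 5 columns in ", path)
  }
  protein <- vapply(fields, `[[`, character(1), 2L)
  term <- vapply(fields, `[[`, character(1), 5L)
  dup <- duplicated(paste(protein, term, sep = "\t"))
  data.frame(protein = protein[!dup], go_slim = term[!dup],
             stringsAsFactors = FALSE)
}

#' Write an annotation table
#'
#' @param annotations Data frame with columns `protein`, `go_slim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(is.data.frame(annotations),
            all(c("protein", "go_slim") %in% names(annotations)))
  writeLines(paste(annotations$protein, annotations$go_slim, sep = "\t"),
             path)
  invisible(path)
}

#' Read a complex file (one complex per line)
#'
#' CYC2008/MIPS convention: whitespace-separated member IDs, one complex per
#' line.  Lines with fewer than two distinct members are skipped with a
#' warning; duplicate members within a line collapse.
#'
#' @param path Path to the complex file.
#' @return A list of character vectors of member IDs (sorted within each
#'   complex).
#' @export
read_complexes <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("complex file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  members <- lapply(strsplit(trimws(lines), "\\s+"), function(x) sort(unique(x)))
  small <- lengths(members) < 2L
  if (any(small)) {
    warning("read_complexes: skipped ", sum(small),
            " line(s) with fewer than 2 members")
  }
  members[!small]
}

#' Write a complex file (one complex per line)
#'
#' @param complexes A list of character vectors of member IDs, or a
#'   [predict_complexes()] result (its member sets are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(complexes, path) {
  complexes <- as_member_list(complexes)
  writeLines(vapply(complexes, paste, character(1), collapse = " "), path)
  invisible(path)
}

## Coerce the various complex containers to a plain list of member vectors.
as_member_list <- function(x) {
  if (inherits(x, "complex_prediction")) return(lapply(x$complexes, `[[`, "members"))
  if (inherits(x, "onto_clique")) return(list(x$members))
  if (is.character(x)) return(list(sort(unique(x))))
  stopifnot(is.list(x))
  lapply(x, function(ci) {
    if (inherits(ci, "onto_clique")) sort(unique(ci$members))
    else if (is.list(ci) && !is.null(ci$members)) sort(unique(ci$members))
    else sort(unique(as.character(ci)))
  })
}
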