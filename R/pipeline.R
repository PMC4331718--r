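#' Predict protein complexes from typed PPI data (two-phase method)
#'
#' Phase 1 estimates the contribution weight of each evidence source from
#' the quality of the seed cliques its single-source network supports (see
#' [compute_source_weights()]); with `weight_mode = "equal"` or `"fixed"`
#' that phase is skipped.  Phase 2 builds the combined attributed network,
#' mines and ranks maximal ontology-correlated cliques, reduces them to a
#' disjoint seed set, and grows each seed into a complex by attaching
#' neighbors whose closeness score reaches `extend_thres`.
#'
#' @param edges Typed edge records: a data frame with columns `protein_a`,
#'   `protein_b`, `source_type` (rows from all sources together), e.g.
#'   `rbind(read_edge_list(f1, "T1"), read_edge_list(f2, "T2"))`.
#' @param annotations Optional annotation data frame (`protein`, `go_slim`).
#' @param weight_mode `"auto"` (default; estimate from the data), `"equal"`,
#'   or `"fixed"` (supply `weights`).
#' @param weights Named weights for `weight_mode = "fixed"` (normalized).
#' @param extend_thres Closeness threshold for attachment in \[0, 1\]
#'   (default 0.1).
#' @param min_clique_size Minimum clique size (default 3).
#' @param seed_method Overlap-reduction rule, see [select_seeds()].
#' @return An object of class `complex_prediction` with components
#'   `complexes` (list of `predicted_complex`), `seeds`, `weights`,
#'   `contribution` (phase-1 report or `NULL`), `network`, `params`,
#'   `counts`.  Methods: `print`, `summary`, `coef` (the source weights),
#'   `plot`, `as.data.frame` (long membership table).
#' @examples
#' syn <- generate_network(synthetic_spec(n_complexes = 3, seed = 7))
#' fit <- predict_complexes(syn$edges, syn$annotations)
#' coef(fit)
#' match_and_score(fit, syn$complexes)
#' @export
predict_complexes <- function(edges, annotations = NULL,
                              weight_mode = c("auto", "equal", "fixed"),
                              weights = NULL, extend_thres = 0.1,
                              min_clique_size = 3L,
                              seed_method = "prune") {
  weight_mode <- match.arg(weight_mode)
  stopifnot(is.data.frame(edges), nrow(edges) >= 1L)
  tags <- sort(unique(as.character(edges$source_type)))
  contribution <- NULL
  if (weight_mode == "auto") {
    by_type <- split(edges, edges$source_type)
    contribution <- compute_source_weights(by_type, annotations,
                                           min_size = min_clique_size,
                                           seed_method = seed_method)
    w <- contribution$weights
  } else if (weight_mode == "equal") {
    w <- source_weights(stats::setNames(rep(1, length(tags)), tags))
  } else {
    if (is.null(weights)) stop("weight_mode = 'fixed' needs 'weights'")
    w <- if (inherits(weights, "source_weights")) weights else
      source_weights(weights)
    if (!all(tags %in% names(w))) {
      stop("fixed weights do not cover all source tags in the data")
    }
  }
  network <- build_network(edges, annotations, type_tags = tags)
  candidates <- generate_candidates(network, w, min_size = min_clique_size)
  seeds <- select_seeds(network, candidates, w, method = seed_method,
                        min_size = min_clique_size)
  complexes <- augment_seeds(network, seeds, w, extend_thres = extend_thres)
  if (length(complexes) == 0L) {
    warning("no candidate cliques with shared annotations: ",
            "prediction is empty")
  }
  structure(list(
    complexes = complexes,
    seeds = seeds,
    weights = w,
    contribution = contribution,
    network = network,
    params = list(weight_mode = weight_mode, extend_thres = extend_thres,
                  min_clique_size = as.integer(min_clique_size),
                  seed_method = seed_method),
    counts = c(edge_records = nrow(edges),
               vertices = length(network$vertices),
               network_edges = nrow(network$edges),
               candidates = length(candidates),
               seeds = length(seeds),
               complexes = length(complexes))
  ), class = "complex_prediction")
}

#' @export
print.complex_prediction <- function(x, ...) {
  cat("Protein complex prediction (", x$params$weight_mode,
      " weights, extend_thres = ", x$params$extend_thres, ")\n", sep = "")
  cat("  source weights: ",
      paste(sprintf("%s = %.3f", names(x$weights), unclass(x$weights)),
            collapse = ", "), "\n", sep = "")
  cat("  ", x$counts[["vertices"]], " vertices, ",
      x$counts[["network_edges"]], " edges -> ",
      x$counts[["candidates"]], " candidates, ",
      x$counts[["seeds"]], " seeds, ",
      x$counts[["complexes"]], " complexes\n", sep = "")
  invisible(x)
}

#' @export
summary.complex_prediction <- function(object, ...) {
  sizes <- lengths(lapply(object$complexes, `[[`, "members"))
  natt <- vapply(object$complexes, function(x) length(x$attachments), integer(1))
  out <- list(counts = object$counts, weights = object$weights,
              params = object$params,
              size_summary = if (length(sizes)) summary(sizes) else NULL,
              n_attachments = sum(natt))
  class(out) <- "summary.complex_prediction"
  out
}

#' @export
print.summary.complex_prediction <- function(x, ...) {
  cat("Complex prediction summary\n")
  print(x$weights)
  cat("  stage counts:\n")
  print(x$counts)
  if (!is.null(x$size_summary)) {
    cat("  complex sizes:\n")
    print(x$size_summary)
  }
  cat("  total attached neighbors:", x$n_attachments, "\n")
  invisible(x)
}

#' @export
coef.complex_prediction <- function(object, ...) unclass(object$weights)

#' @export
as.data.frame.complex_prediction <- function(x, ...) {
  if (length(x$complexes) == 0L) {
    return(data.frame(complex = integer(), member = character(),
                      role = character(), closeness = numeric()))
  }
  do.call(rbind, lapply(seq_along(x$complexes), function(i) {
    cx <- x$complexes[[i]]
    role <- ifelse(cx$members %in% cx$seed$members, "seed", "attachment")
    clo <- rep(NA_real_, length(cx$members))
    clo[match(names(cx$attachments), cx$members)] <- unname(cx$attachments)
    data.frame(complex = i, member = cx$members, role = role,
               closeness = clo, stringsAsFactors = FALSE)
  }))
}

#' @export
plot.complex_prediction <- function(x, ...) {
  if (length(x$complexes) == 0L) {
    warning("nothing to plot: empty prediction")
    return(invisible(x))
  }
  seed_sizes <- lengths(lapply(x$complexes, function(c) c$seed$members))
  att <- vapply(x$complexes, function(c) length(c$attachments), integer(1))
  ord <- order(-(seed_sizes + att))
  graphics::barplot(rbind(seed = seed_sizes[ord], attachment = att[ord]),
                    names.arg = ord, legend.text = c("seed", "attached"),
                    xlab = "predicted complex", ylab = "members",
                    main = "Predicted complex composition", ...)
  invisible(x)
}

#' Assemble a run configuration
#'
#' Collects paths and parameters for a file-based prediction run.
#'
#' @param ht_edges,lit_edges Paths to the high-throughput and literature
#'   edge lists (`lit_edges` may be `NULL` for a single-source run).
#' @param annotations Optional path to the annotation table.
#' @param benchmark Optional path to a benchmark complex file; when given,
#'   [run_predict()] also writes an evaluation report.
#' @param out Output directory (created if missing).
#' @param extend_thres,na_threshold,min_clique_size,weight_mode,weights,seed
#'   Pipeline parameters; `weight_mode` is `"auto"`, `"equal"` or `"fixed"`
#'   (with `weights` a numeric `c(T1 = ..., T2 = ...)`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(ht_edges, lit_edges = NULL, annotations = NULL,
                       benchmark = NULL, out = ".", extend_thres = 0.1,
                       na_threshold = 0.2, min_clique_size = 3L,
                       weight_mode = "auto", weights = NULL, seed = 1L) {
  stopifnot(extend_thres >= 0, extend_thres <= 1,
            na_threshold >= 0, na_threshold <= 1, min_clique_size >= 2L)
  structure(list(ht_edges = ht_edges, lit_edges = lit_edges,
                 annotations = annotations, benchmark = benchmark, out = out,
                 extend_thres = extend_thres, na_threshold = na_threshold,
                 min_clique_size = as.integer(min_clique_size),
                 weight_mode = weight_mode, weights = weights,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a flat YAML run configuration
#'
#' Keys mirror the [run_config()] arguments; unknown keys are rejected.
#'
#' @param path Path to a flat key-value YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$weights)) raw$weights <- unlist(raw$weights)
  do.call(run_config, raw)
}

#' Run a file-based prediction (phase 1 + phase 2)
#'
#' Reads the typed edge lists and annotations named in the config, runs
#' [predict_complexes()], and writes to `config$out`: `complexes.txt` (one
#' complex per line), `attachments.tsv` (per-member roles and closeness
#' scores), `report.txt` (a reproducible key-value run report: config echo,
#' estimated weights, stage counts, package version), and — when a
#' benchmark is configured — `evaluation.tsv`.
#'
#' @param config A [run_config()].
#' @return The `complex_prediction`, invisibly.
#' @export
run_predict <- function(config) {
  stopifnot(inherits(config, "run_config"))
  edges <- read_edge_list(config$ht_edges, "T1")
  if (!is.null(config$lit_edges)) {
    edges <- rbind(edges, read_edge_list(config$lit_edges, "T2"))
  }
  ann <- if (!is.null(config$annotations)) read_annotations(config$annotations)
  fit <- predict_complexes(edges, ann, weight_mode = config$weight_mode,
                           weights = config$weights,
                           extend_thres = config$extend_thres,
                           min_clique_size = config$min_clique_size)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_complexes(fit, file.path(config$out, "complexes.txt"))
  utils::write.table(as.data.frame(fit),
                     file.path(config$out, "attachments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rep_lines <- c(
    paste0("package: ontoclique ",
           as.character(utils::packageVersion("ontoclique"))),
    paste0("ht_edges: ", config$ht_edges),
    paste0("lit_edges: ", if (is.null(config$lit_edges)) "" else config$lit_edges),
    paste0("annotations: ",
           if (is.null(config$annotations)) "" else config$annotations),
    paste0("weight_mode: ", config$weight_mode),
    paste0("extend_thres: ", config$extend_thres),
    paste0("na_threshold: ", config$na_threshold),
    paste0("min_clique_size: ", config$min_clique_size),
    paste0("seed: ", config$seed),
    paste0("weights: ",
           paste(sprintf("%s=%.6f", names(fit$weights), unclass(fit$weights)),
                 collapse = " ")),
    paste0("counts: ",
           paste(sprintf("%s=%d", names(fit$counts), fit$counts),
                 collapse = " "))
  )
  if (!is.null(fit$contribution)) {
    tb <- fit$contribution$table
    rep_lines <- c(rep_lines,
      sprintf("c_degree_%s: %.6f (n_edges=%d)", tb$type, tb$c_degree,
              tb$n_edges))
  }
  writeLines(rep_lines, file.path(config$out, "report.txt"))
  if (!is.null(config$benchmark)) {
    run_evaluate(file.path(config$out, "complexes.txt"), config$benchmark,
                 na_threshold = config$na_threshold,
                 out = file.path(config$out, "evaluation.tsv"))
  }
  invisible(fit)
}

#' Evaluate a prediction file against a benchmark file
#'
#' @param predictions Path to a complex file of predictions.
#' @param benchmark Path to the benchmark complex file.
#' @param na_threshold Match threshold (default 0.2).
#' @param out Optional path for a TSV report.
#' @return The `evaluation_report` (all-zero with a warning when the
#'   prediction file is empty).
#' @export
run_evaluate <- function(predictions, benchmark, na_threshold = 0.2,
                         out = NULL) {
  pred <- read_complexes(predictions)
  bench <- read_complexes(benchmark)
  if (length(pred) == 0L) {
    warning("empty prediction file: reporting zero metrics")
    report <- structure(list(
      n_predicted = 0L, n_predicted_raw = 0L, n_benchmark = length(bench),
      na_threshold = na_threshold,
      matches = data.frame(predicted = integer(), benchmark = integer(),
                           na = numeric()),
      precision = 0, recall = 0, f_score = 0, sn = 0, ppv = 0, acc = 0
    ), class = "evaluation_report")
  } else {
    report <- match_and_score(pred, bench, na_threshold = na_threshold)
  }
  if (!is.null(out)) write_evaluation(report, out)
  report
}

#' Sweep the attachment threshold
#'
#' Runs phase 1 and seed selection once, then re-augments the same seeds at
#' each `extend_thres` value and scores against the benchmark — the
#' threshold-sensitivity protocol.
#'
#' @inheritParams predict_complexes
#' @param benchmark List of benchmark member vectors (or a complex-file
#'   path).
#' @param thresholds Threshold grid (default 0.05 and 0.1..1.0 by 0.1).
#' @param na_threshold Match threshold for scoring (default 0.2).
#' @return A data frame with one row per threshold: `extend_thres`,
#'   `n_complexes`, `P`, `R`, `F`, `Sn`, `PPV`, `Acc`.
#' @export
sweep_extend_thres <- function(edges, annotations, benchmark,
                               thresholds = c(0.05, seq(0.1, 1, by = 0.1)),
                               weight_mode = "auto", weights = NULL,
                               min_clique_size = 3L, na_threshold = 0.2) {
  if (is.character(benchmark) && length(benchmark) == 1L) {
    benchmark <- read_complexes(benchmark)
  }
  fit <- predict_complexes(edges, annotations, weight_mode = weight_mode,
                           weights = weights,
                           min_clique_size = min_clique_size)
  rows <- lapply(thresholds, function(th) {
    cx <- augment_seeds(fit$network, fit$seeds, fit$weights,
                        extend_thres = th)
    if (length(cx) == 0L) {
      return(data.frame(extend_thres = th, n_complexes = 0L, P = 0, R = 0,
                        F = 0, Sn = 0, PPV = 0, Acc = 0))
    }
    rep <- match_and_score(lapply(cx, `[[`, "members"), benchmark,
                           na_threshold = na_threshold)
    data.frame(extend_thres = th, n_complexes = rep$n_predicted,
               P = rep$precision, R = rep$recall, F = rep$f_score,
               Sn = rep$sn, PPV = rep$ppv, Acc = rep$acc)
  })
  do.call(rbind, rows)
}
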