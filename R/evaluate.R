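#' Neighborhood affinity between two complexes
#'
#' NA(P, B) = |P ∩ B|^2 / (|P| x |B|): 1 for identical member sets, 0 for
#' disjoint ones, symmetric in its arguments.
#'
#' @param P,B Non-empty character vectors of member IDs.
#' @return A scalar in \[0, 1\].
#' @export
neighborhood_affinity <- function(P, B) {
  P <- unique(as.character(P)); B <- unique(as.character(B))
  if (length(P) == 0L || length(B) == 0L) {
    stop("neighborhood affinity of an empty complex is undefined")
  }
  length(intersect(P, B))^2 / (length(P) * length(B))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return 2 P R / (P + R), with 0 where P + R = 0.
#' @export
f_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Geometric-mean accuracy of Sn and PPV
#'
#' @param sn,ppv Numeric vectors in \[0, 1\] (clustering-wise sensitivity and
#'   positive predictive value).
#' @return sqrt(Sn x PPV).
#' @export
acc_score <- function(sn, ppv) sqrt(sn * ppv)

#' Match predictions to a benchmark and compute all metrics
#'
#' A predicted complex matches a benchmark complex when their
#' [neighborhood_affinity()] is strictly greater than `na_threshold`.
#' Precision is the fraction of predictions matching at least one benchmark
#' complex; recall the fraction of benchmark complexes matched by at least
#' one prediction; F their harmonic mean.  Sn, PPV and Acc are the
#' clustering-wise statistics of the overlap table t_ij = |B_i ∩ P_j|:
#' Sn = sum_i max_j t_ij / sum_i |B_i|, PPV = sum_j max_i t_ij /
#' sum_j sum_i t_ij (0 if the denominator is 0), Acc = sqrt(Sn x PPV).
#' Predictions with fewer than two members are excluded up front (a complex
#' is by definition at least two proteins) with a message.
#'
#' @param predicted,benchmark Non-empty lists of member-ID vectors (a
#'   [predict_complexes()] result is accepted for `predicted`).
#' @param na_threshold Match threshold on NA (default 0.2; matching is
#'   strict, NA exactly equal to the threshold does not match).
#' @return An object of class `evaluation_report`.
#' @examples
#' rep <- match_and_score(list(c("A", "B")), list(c("A", "B", "C")))
#' rep$sn   # 2/3
#' rep$ppv  # 1
#' @export
match_and_score <- function(predicted, benchmark, na_threshold = 0.2) {
  predicted <- as_member_list(predicted)
  benchmark <- as_member_list(benchmark)
  if (length(predicted) == 0L || length(benchmark) == 0L) {
    stop("both the predicted and the benchmark complex lists must be non-empty")
  }
  n_raw <- length(predicted)
  sizes <- lengths(predicted)
  if (any(sizes < 2L)) {
    message("match_and_score: excluded ", sum(sizes < 2L),
            " prediction(s) with fewer than 2 members")
    predicted <- predicted[sizes >= 2L]
  }
  if (length(predicted) == 0L) {
    stop("no prediction with >= 2 members left to evaluate")
  }
  np <- length(predicted); nb <- length(benchmark)
  ## overlap table t[i, j] = |B_i ∩ P_j|
  t_ij <- matrix(0L, nrow = nb, ncol = np)
  na_ij <- matrix(0, nrow = nb, ncol = np)
  for (i in seq_len(nb)) {
    for (j in seq_len(np)) {
      ov <- length(intersect(benchmark[[i]], predicted[[j]]))
      t_ij[i, j] <- ov
      na_ij[i, j] <- ov^2 / (length(predicted[[j]]) * length(benchmark[[i]]))
    }
  }
  hit <- na_ij > na_threshold
  precision <- sum(colSums(hit) > 0) / np
  recall <- sum(rowSums(hit) > 0) / nb
  sn <- sum(apply(t_ij, 1L, max)) / sum(lengths(benchmark))
  tot <- sum(t_ij)
  ppv <- if (tot > 0) sum(apply(t_ij, 2L, max)) / tot else 0
  idx <- which(hit, arr.ind = TRUE)
  matches <- data.frame(predicted = idx[, "col"], benchmark = idx[, "row"],
                        na = na_ij[idx], row.names = NULL)
  matches <- matches[order(matches$predicted, matches$benchmark), , drop = FALSE]
  rownames(matches) <- NULL
  structure(list(
    n_predicted = np, n_predicted_raw = n_raw, n_benchmark = nb,
    na_threshold = na_threshold, matches = matches,
    precision = precision, recall = recall,
    f_score = f_score(precision, recall),
    sn = sn, ppv = ppv, acc = acc_score(sn, ppv)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Complex prediction evaluation (NA >", x$na_threshold, "match rule)\n")
  cat("  predictions:", x$n_predicted,
      if (x$n_predicted_raw != x$n_predicted)
        paste0("(of ", x$n_predicted_raw, " raw)") else "",
      " benchmark:", x$n_benchmark, "\n")
  cat(sprintf("  P = %.3f  R = %.3f  F = %.3f\n",
              x$precision, x$recall, x$f_score))
  cat(sprintf("  Sn = %.3f  PPV = %.3f  Acc = %.3f\n", x$sn, x$ppv, x$acc))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row with columns `n_complexes`, `P`, `R`, `F`, `Sn`, `PPV`, `Acc`
#' (plus the raw prediction count before size filtering).
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  df <- data.frame(n_complexes = report$n_predicted,
                   n_complexes_raw = report$n_predicted_raw,
                   P = report$precision, R = report$recall, F = report$f_score,
                   Sn = report$sn, PPV = report$ppv, Acc = report$acc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
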