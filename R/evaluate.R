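#' Example-based metrics for one document
#'
#' Multi-label precision, recall, F-measure and accuracy of a predicted
#' label set Z against the gold set Y:
#' `p = |Y n Z| / |Z|`, `r = |Y n Z| / |Y|`, `f = 2|Y n Z| / (|Y| + |Z|)`,
#' `acc = |Y n Z| / |Y u Z|`. An empty prediction has precision 0 by
#' convention.
#'
#' With `literal_f = TRUE` the F-measure drops the factor 2
#' (`|Y n Z| / (|Y| + |Z|)`), i.e. exactly half the harmonic-mean value;
#' this variant is exposed for comparison only, the default is the
#' standard definition.
#'
#' @param Y character vector of true labels (non-empty).
#' @param Z character vector of predicted labels (may be empty).
#' @param literal_f use the halved F variant (default `FALSE`).
#' @return named numeric vector `precision`, `recall`, `f`, `accuracy`.
#' @export
example_metrics <- function(Y, Z, literal_f = FALSE) {
  Y <- unique(as.character(Y)); Z <- unique(as.character(Z))
  if (length(Y) == 0L) {
    stop("true label set is empty; such documents must be excluded",
         call. = FALSE)
  }
  inter <- length(intersect(Y, Z))
  p <- if (length(Z) == 0L) 0 else inter / length(Z)
  r <- inter / length(Y)
  f <- (if (literal_f) 1 else 2) * inter / (length(Y) + length(Z))
  acc <- inter / length(union(Y, Z))
  c(precision = p, recall = r, f = f, accuracy = acc)
}

#' Aggregate example-based metrics over a test set
#'
#' Computes the per-document metrics of [example_metrics()] and their
#' arithmetic means (EBP, EBR, EBF, Acc) over the m evaluated documents,
#' plus the micro-averaged F over all label decisions,
#' `MiF = 2 TP / (2 TP + FP + FN)` with the counts summed over documents.
#' Documents with an empty gold set are excluded and counted.
#'
#' @param truth list of character vectors: gold label sets.
#' @param predicted list of character vectors: predicted label sets (same
#'   length and order).
#' @param doc_ids optional document ids for the per-document table.
#' @param literal_f passed to [example_metrics()].
#' @return an `eval_report`: list with `m`, `EBP`, `EBR`, `EBF`, `Acc`,
#'   `MiF`, `n_excluded` and the tibble `per_doc`.
#' @export
evaluate_predictions <- function(truth, predicted, doc_ids = NULL,
                                 literal_f = FALSE) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(doc_ids)) doc_ids <- as.character(seq_along(truth))
  keep <- lengths(truth) > 0L
  n_excluded <- sum(!keep)
  truth <- truth[keep]; predicted <- predicted[keep]; doc_ids <- doc_ids[keep]
  m <- length(truth)
  if (m == 0L) stop("no document with a non-empty gold label set", call. = FALSE)
  per <- t(vapply(seq_len(m), function(i) {
    example_metrics(truth[[i]], predicted[[i]], literal_f = literal_f)
  }, c(precision = 0, recall = 0, f = 0, accuracy = 0)))
  tp <- sum(vapply(seq_len(m), function(i) {
    length(intersect(unique(truth[[i]]), unique(predicted[[i]])))
  }, numeric(1)))
  n_pred <- sum(vapply(predicted, function(z) length(unique(z)), numeric(1)))
  n_true <- sum(vapply(truth, function(y) length(unique(y)), numeric(1)))
  fp <- n_pred - tp; fn <- n_true - tp
  mif <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(
    list(m = m, EBP = mean(per[, "precision"]), EBR = mean(per[, "recall"]),
         EBF = mean(per[, "f"]), Acc = mean(per[, "accuracy"]), MiF = mif,
         n_excluded = n_excluded,
         per_doc = tibble::tibble(doc_id = doc_ids,
                                  precision = per[, "precision"],
                                  recall = per[, "recall"],
                                  f = per[, "f"],
                                  accuracy = per[, "accuracy"])),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("<eval_report> m =", x$m,
      if (x$n_excluded > 0) paste0("(", x$n_excluded, " excluded: empty gold set)"),
      "\n")
  cat(sprintf("  EBP = %.*f  EBR = %.*f  EBF = %.*f  Acc = %.*f  MiF = %.*f\n",
              digits, x$EBP, digits, x$EBR, digits, x$EBF, digits, x$Acc,
              digits, x$MiF))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Per-document rows followed by a `__summary__` row with the corpus
#' means and MiF.
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  per <- as.data.frame(report$per_doc)
  per$MiF <- NA_real_
  summary_row <- data.frame(doc_id = "__summary__", precision = report$EBP,
                            recall = report$EBR, f = report$EBF,
                            accuracy = report$Acc, MiF = report$MiF,
                            stringsAsFactors = FALSE)
  utils::write.table(rbind(per, summary_row), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
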