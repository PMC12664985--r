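#' Classification metrics from predictions and ground truth
#'
#' Builds per-class one-vs-rest confusion counts and the standard metric
#' set: precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic
#' mean, macro F1 the unweighted mean of per-class F1 scores, and weighted
#' F1 the support-weighted mean. An `"unknown"` prediction is counted as a
#' missed detection for its true class (it enters the recall denominator)
#' and is never a false positive for any class; unknowns are tallied
#' separately so confusion totals remain consistent.
#'
#' @param predictions Tibble with `id` and `predicted` columns (e.g. from
#'   [classify_fasta()]), or a bare character vector of predicted labels.
#' @param truths Tibble with `id` and `class` columns, or a character vector
#'   aligned with `predictions`.
#' @param classes Class order; defaults to the sorted classes present in
#'   the truth.
#' @return Object of class `tag_metrics`: list with `per_class` (tibble:
#'   class, n, tp, fp, fn, tn, unknown, precision, recall, f1), `accuracy`,
#'   `macro_f1`, `weighted_f1`, `n`, `n_unknown`.
#' @examples
#' m <- compute_metrics(c("a", "a", "b"), c("a", "b", "b"))
#' m$macro_f1
#' @export
compute_metrics <- function(predictions, truths, classes = NULL) {
  if (is.data.frame(predictions)) {
    if (is.data.frame(truths)) {
      miss <- setdiff(predictions$id, truths$id)
      if (length(miss))
        abort(paste0("no truth for prediction ids: ", toString(utils::head(miss, 5))))
      truth <- truths$class[match(predictions$id, truths$id)]
    } else {
      truth <- truths
    }
    pred <- predictions$predicted
  } else {
    pred <- predictions
    truth <- if (is.data.frame(truths)) truths$class else truths
  }
  if (length(pred) != length(truth))
    abort("predictions and truths differ in length")
  if (is.null(classes)) classes <- sort(unique(truth))
  n <- length(pred)
  unk <- pred == "unknown"

  per <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl & !unk)
    u <- sum(unk & truth == cl)
    tn <- n - tp - fp - fn - u
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn + u == 0) 0 else tp / (tp + fn + u)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble::tibble(class = cl, n = sum(truth == cl), tp = tp, fp = fp,
                   fn = fn, tn = tn, unknown = u,
                   precision = prec, recall = rec, f1 = f1)
  })
  per <- dplyr::bind_rows(per)
  structure(list(
    per_class = per,
    accuracy = mean(pred == truth),
    macro_f1 = mean(per$f1),
    weighted_f1 = sum(per$f1 * per$n) / sum(per$n),
    n = n,
    n_unknown = sum(unk)
  ), class = "tag_metrics")
}

#' @export
print.tag_metrics <- function(x, ...) {
  cat(sprintf("<tag_metrics> n=%d  accuracy=%.4f  macro F1=%.4f  weighted F1=%.4f  unknown=%d\n",
              x$n, x$accuracy, x$macro_f1, x$weighted_f1, x$n_unknown))
  print(x$per_class)
  invisible(x)
}
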