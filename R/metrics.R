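#' Shuffled k-fold split
#'
#' Partitions `1:n_samples` into `k` disjoint, shuffled test-index sets
#' whose sizes differ by at most one. Deterministic given `seed`.
#'
#' @param n_samples Number of samples (must be at least `k`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A list of `k` integer vectors.
#' @export
kfold_split <- function(n_samples, k = 5, seed = 1) {
  if (n_samples < k) abort(sprintf("cannot split %d samples into %d folds", n_samples, k))
  idx <- withr::with_seed(seed, sample.int(n_samples))
  unname(lapply(split(idx, rep(seq_len(k), length.out = n_samples)), sort))
}

#' Confusion matrix with a fixed class set
#'
#' @param truth,pred Vectors (coerced to factors over `classes`).
#' @param classes Class levels; rows of the result are truth, columns are
#'   predictions.
#' @return An integer matrix with dimnames.
#' @export
confusion_matrix <- function(truth, pred, classes) {
  classes <- as.character(classes)
  t_f <- factor(as.character(truth), levels = classes)
  p_f <- factor(as.character(pred), levels = classes)
  if (anyNA(t_f) || anyNA(p_f)) abort("labels outside the class set")
  m <- table(truth = t_f, predicted = p_f)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(truth = classes, predicted = classes))
}

#' Macro-averaged classification metrics from a confusion matrix
#'
#' Treats each class one-vs-rest: from the confusion matrix (rows = truth,
#' columns = predictions) it derives TP, FP, TN, FN per class and computes
#' per-class accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, specificity
#' `TN/(TN+FP)`, recall `TP/(TP+FN)` and F1; the macro value of each
#' metric is the unweighted mean over classes. A per-class metric with a
#' zero denominator is defined as 0, and classes absent from both truth
#' and predictions are flagged in the result.
#'
#' @param confusion Square non-negative count matrix.
#' @return A list of class `macro_metrics`: `macro` (one-row tibble),
#'   `per_class` (tibble with the counts and metrics), and `absent`
#'   (character vector of flagged classes).
#' @export
macro_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) abort("confusion matrix must be square")
  if (any(confusion < 0)) abort("confusion matrix must be non-negative")
  n <- sum(confusion)
  if (n == 0) abort("confusion matrix is all zero")
  classes <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))

  tp <- unname(diag(confusion))
  fn <- unname(rowSums(confusion)) - tp
  fp <- unname(colSums(confusion)) - tp
  tn <- n - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)

  per_class <- tibble::tibble(
    class = classes, tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / n,
    precision = safe(tp, tp + fp),
    specificity = safe(tn, tn + fp),
    recall = safe(tp, tp + fn),
    f1 = safe(2 * precision * recall, precision + recall),
    present = (tp + fn + fp) > 0
  )
  macro <- dplyr::summarise(per_class, dplyr::across(
    c("accuracy", "precision", "specificity", "recall", "f1"), mean))
  structure(list(macro = macro, per_class = per_class,
                 absent = classes[!per_class$present]),
            class = "macro_metrics")
}

#' @export
print.macro_metrics <- function(x, ...) {
  cat("macro-averaged metrics over", nrow(x$per_class), "classes:\n")
  print(as.data.frame(x$macro), row.names = FALSE, digits = 4)
  if (length(x$absent)) {
    cat("flag: class(es) absent from truth and predictions (scored 0):",
        paste(x$absent, collapse = ", "), "\n")
  }
  invisible(x)
}
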