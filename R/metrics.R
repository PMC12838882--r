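#' Confusion matrix over the five sleep stages
#'
#' Rows are the reference (human-scored) stages, columns the predicted stages,
#' both in the fixed order W, N1, N2, N3, REM.
#'
#' @param reference,predicted equal-length label vectors over the five-stage
#'   vocabulary (character or factor).
#' @return 5 x 5 integer matrix of counts; entry `(a, b)` is the number of
#'   epochs with reference stage `a` predicted as `b`.
#' @export
confusion_matrix <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop("reference and predicted label vectors have different lengths")
  }
  r <- stage_factor(reference)
  p <- stage_factor(predicted)
  m <- table(reference = r, predicted = p)
  cm <- matrix(as.integer(m), nrow = 5, dimnames = list(
    reference = SLEEP_STAGES, predicted = SLEEP_STAGES
  ))
  cm
}

check_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(5L, 5L)) || any(confusion < 0)) {
    stop("confusion must be a nonnegative 5 x 5 count matrix")
  }
  if (sum(confusion) < 1) stop("confusion matrix is empty (no scored epochs)")
  confusion
}

#' Overall accuracy from a confusion matrix
#'
#' Multi-class accuracy: the fraction of scored epochs on the diagonal
#' (trace / total).
#'
#' @param confusion 5 x 5 count matrix, rows = reference.
#' @return scalar in \[0, 1\].
#' @export
accuracy <- function(confusion) {
  confusion <- check_confusion(confusion)
  sum(diag(confusion)) / sum(confusion)
}

# one-vs-rest tallies for class i: TP, FP, FN
class_tallies <- function(confusion, i) {
  tp <- confusion[i, i]
  fp <- sum(confusion[, i]) - tp
  fn <- sum(confusion[i, ]) - tp
  c(tp = tp, fp = fp, fn = fn)
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest counts per stage: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 the harmonic mean of the two. A zero denominator yields 0 and raises the
#' `degenerate` flag (attribute) so that macro-F1 stays defined on degenerate
#' splits.
#'
#' @param confusion 5 x 5 count matrix, rows = reference.
#' @param class stage name or index 1..5.
#' @return named numeric `c(precision, recall, f1)`, with attribute
#'   `degenerate` (logical).
#' @export
class_f1 <- function(confusion, class) {
  confusion <- check_confusion(confusion)
  if (is.character(class)) class <- match(class, SLEEP_STAGES)
  t <- class_tallies(confusion, class)
  degen <- FALSE
  pr <- if (t["tp"] + t["fp"] > 0) t["tp"] / (t["tp"] + t["fp"]) else { degen <- TRUE; 0 }
  re <- if (t["tp"] + t["fn"] > 0) t["tp"] / (t["tp"] + t["fn"]) else { degen <- TRUE; 0 }
  f1 <- if (pr + re > 0) 2 * pr * re / (pr + re) else { degen <- TRUE; 0 }
  out <- c(precision = unname(pr), recall = unname(re), f1 = unname(f1))
  attr(out, "degenerate") <- degen
  out
}

#' Macro-averaged F1 (MF1)
#'
#' Unweighted mean of the five per-class F1 scores.
#'
#' @inheritParams accuracy
#' @return scalar in \[0, 1\].
#' @export
macro_f1 <- function(confusion) {
  confusion <- check_confusion(confusion)
  mean(vapply(1:5, function(i) class_f1(confusion, i)[["f1"]], numeric(1)))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed agreement (accuracy) and p_e the expected agreement from the
#' product of row and column marginals.
#'
#' @inheritParams accuracy
#' @return scalar in \[-1, 1\]; `NA` with a warning when p_e = 1 (both raters
#'   stuck on a single identical class), where kappa is undefined.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- check_confusion(confusion)
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) {
    warning("Cohen's kappa undefined: chance agreement p_e = 1 ",
            "(all mass on one identical class)")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Full evaluation report
#'
#' @param reference,predicted equal-length stage label vectors.
#' @return object of class `metrics_report`: list with `confusion`,
#'   `accuracy`, `per_class` (5 x 3 matrix of precision/recall/F1), `mf1`,
#'   `kappa`, `n`.
#' @export
metrics_report <- function(reference, predicted) {
  cm <- confusion_matrix(reference, predicted)
  per_class <- t(vapply(1:5, function(i) class_f1(cm, i), numeric(3)))
  rownames(per_class) <- SLEEP_STAGES
  out <- list(
    confusion = cm,
    accuracy = accuracy(cm),
    per_class = per_class,
    mf1 = macro_f1(cm),
    kappa = suppressWarnings(cohens_kappa(cm)),
    n = sum(cm)
  )
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sleep staging evaluation over %d epochs\n", x$n))
  cat(sprintf("  accuracy: %.4f   MF1: %.4f   kappa: %.4f\n",
              x$accuracy, x$mf1, x$kappa))
  cat("  per-class F1: ",
      paste(sprintf("%s=%.3f", SLEEP_STAGES, x$per_class[, "f1"]),
            collapse = "  "), "\n")
  cat("  confusion (rows = reference):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
write_metrics_json <- function(report, path = NULL) {
  obj <- list(
    n = report$n,
    accuracy = report$accuracy,
    mf1 = report$mf1,
    kappa = report$kappa,
    per_class = as.data.frame(report$per_class),
    confusion = unname(apply(report$confusion, 1, identity, simplify = FALSE))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
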