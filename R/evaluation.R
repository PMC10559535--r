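#' Confusion matrix with fixed orientation
#'
#' Rows are the true label (0 = benign hyperplasia on top, 1 = prostate
#' cancer below), columns the predicted label (0 left, 1 right), so the
#' false-negative count sits in the lower-left cell and the false-positive
#' count in the upper-right. The orientation is printed on every report.
#'
#' @param y_true,y_pred equal-length vectors of labels in `{0, 1}`.
#' @return a 2 x 2 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (any(is.na(y_true)) || any(is.na(y_pred)) ||
      !all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  cm <- matrix(0L, 2L, 2L,
               dimnames = list(true = c("0", "1"), predicted = c("0", "1")))
  for (i in 1:2) for (j in 1:2) {
    cm[i, j] <- sum(y_true == i - 1L & y_pred == j - 1L)
  }
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows: true 0=HBP / 1=CaP; columns: predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (trace over total) and per-class precision, recall, F1 and
#' support. A zero denominator (empty predicted column, empty true row, or
#' precision + recall = 0) yields 0 with a warning instead of NaN.
#'
#' @param cm a [confusion()] matrix.
#' @return an object of class `metrics_report`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- vapply(1:2, function(j)
    safe_div(cm[j, j], sum(cm[, j]), paste0("precision of class ", j - 1L)),
    numeric(1L))
  recall <- vapply(1:2, function(i)
    safe_div(cm[i, i], sum(cm[i, ]), paste0("recall of class ", i - 1L)),
    numeric(1L))
  f1 <- vapply(1:2, function(k) {
    s <- precision[k] + recall[k]
    if (s == 0) 0 else 2 * precision[k] * recall[k] / s
  }, numeric(1L))
  structure(list(accuracy = sum(diag(cm)) / total,
                 precision = stats::setNames(precision, c("0", "1")),
                 recall = stats::setNames(recall, c("0", "1")),
                 f1 = stats::setNames(f1, c("0", "1")),
                 support = stats::setNames(rowSums(cm), c("0", "1")),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("Accuracy: %.4f\n", x$accuracy))
  tab <- data.frame(class = c("0 (HBP)", "1 (CaP)"),
                    precision = round(x$precision, 4),
                    recall = round(x$recall, 4),
                    f1 = round(x$f1, 4),
                    support = x$support)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Majority-vote patient-level label
#'
#' Aggregates instance predictions to one label per patient by majority
#' vote; exact ties resolve to class 1 (favouring sensitivity). An optional
#' extension beyond the instance-level evaluation.
#'
#' @param y_pred instance-level predicted labels in `{0, 1}`.
#' @param patient_id matching patient identifiers.
#' @return named integer vector, one label per patient.
#' @export
patient_vote <- function(y_pred, patient_id) {
  stopifnot(length(y_pred) == length(patient_id))
  y_pred <- as.integer(y_pred)
  votes <- tapply(y_pred, patient_id, function(v) {
    n1 <- sum(v == 1L)
    if (n1 >= length(v) - n1) 1L else 0L
  })
  out <- as.integer(votes)
  names(out) <- names(votes)
  out
}
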