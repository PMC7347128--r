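#' Confusion matrix of predicted vs actual blight labels
#'
#' @param predicted,actual Equal-length 0/1 vectors.
#' @return A `blight_confusion` object holding the four cells: `tp`
#'   (predicted blight & actual blight), `fp` (predicted blight & actual
#'   non-blight), `fn`, `tn`.
#' @export
#' @examples
#' confusion(c(1, 0), c(1, 0))
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop_data("confusion: predicted and actual differ in length")
  }
  if (!all(predicted %in% c(0, 1)) || !all(actual %in% c(0, 1))) {
    stop_data("confusion: labels must be 0/1")
  }
  confusion_cells(
    tp = sum(predicted == 1 & actual == 1),
    fp = sum(predicted == 1 & actual == 0),
    fn = sum(predicted == 0 & actual == 1),
    tn = sum(predicted == 0 & actual == 0)
  )
}

#' Build a confusion matrix from its four cells
#'
#' Useful for re-deriving metrics from published counts.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A `blight_confusion` object.
#' @export
confusion_cells <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop_data("confusion_cells: cells must be non-negative integers")
  }
  structure(as.list(cells), class = "blight_confusion")
}

#' @export
print.blight_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("blight", "non-blight"),
                              actual = c("blight", "non-blight")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' All five standard metrics, each on the 0–100 percent scale:
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
#' accuracy = (tp+tn)/n, ppv = tp/(tp+fp), npv = tn/(tn+fn).
#' A metric whose denominator is zero is reported `NA` (undefined), never
#' 0. Note for readers of published 311-blight validation tables: labels
#' like "PPV (Sensitivity)" / "NPV (Specificity)" sometimes conflate the
#' row-wise and column-wise rates — the printed percentages there match
#' column-wise sensitivity/specificity, which is what those tables'
#' arithmetic reproduces here under the standard names.
#'
#' @param cm A `blight_confusion`.
#' @param digits Optional rounding for display (e.g. 0 for nearest
#'   percent); default `NULL` reports full precision.
#' @return One-row tibble: the four cells, `n`, `prevalence_pct`, and the
#'   five metrics as `*_pct` columns.
#' @export
#' @examples
#' confusion_metrics(confusion_cells(210413, 43701, 20718, 54211), digits = 0)
confusion_metrics <- function(cm, digits = NULL) {
  stopifnot(inherits(cm, "blight_confusion"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0) stop_data("confusion_metrics: empty confusion matrix")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- tibble::tibble(
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn, n = n,
    prevalence_pct = rate(cm$tp + cm$fn, n),
    sensitivity_pct = rate(cm$tp, cm$tp + cm$fn),
    specificity_pct = rate(cm$tn, cm$tn + cm$fp),
    accuracy_pct = rate(cm$tp + cm$tn, n),
    ppv_pct = rate(cm$tp, cm$tp + cm$fp),
    npv_pct = rate(cm$tn, cm$tn + cm$fn)
  )
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::ends_with("_pct"),
                                            ~ round(.x, digits)))
  }
  out
}

#' Evaluate a fitted model on holdout calls
#'
#' Predicts, thresholds, tabulates the confusion matrix against the true
#' labels, and returns the metric row.
#'
#' @param model A `blight_model`.
#' @param holdout Scored, labelled call tibble.
#' @param threshold Classification cutoff (see [classify()]).
#' @return List with `confusion` (a `blight_confusion`) and `metrics`
#'   (a one-row tibble, full precision).
#' @export
evaluate_model <- function(model, holdout, threshold = 0.5) {
  p <- predict_proba(model, holdout)
  pred <- classify(p, threshold)
  cm <- confusion(pred, holdout$blight_label)
  list(confusion = cm, metrics = confusion_metrics(cm))
}
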