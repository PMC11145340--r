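# Slide-level evaluation: confusion counts and the four headline
# percentages (accuracy, specificity, sensitivity, precision).

#' Confusion matrix of binary slide predictions
#'
#' Positives are cancerous slides (label 1): `TP` counts GT = 1 with
#' PreCls = 1, `TN` GT = 0 with PreCls = 0, `FP` GT = 0 predicted 1,
#' `FN` GT = 1 predicted 0.
#'
#' @param gt ground-truth labels, each 0 or 1
#' @param pred predicted labels, same length
#' @return object of class `confusion_matrix` (list with `TP`, `TN`,
#'   `FP`, `FN`)
#' @export
confusion <- function(gt, pred) {
  if (length(gt) != length(pred)) stop("gt and pred lengths differ")
  if (!all(gt %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  structure(list(TP = sum(gt == 1L & pred == 1L),
                 TN = sum(gt == 0L & pred == 0L),
                 FP = sum(gt == 0L & pred == 1L),
                 FN = sum(gt == 1L & pred == 0L)),
            class = "confusion_matrix")
}

#' Confusion matrix implied by printed specificity and sensitivity
#'
#' On a test set of `n_neg` normal and `n_pos` cancerous slides, a
#' printed specificity fixes `TN = SP/100 * n_neg` and a printed
#' sensitivity fixes `TP = SE/100 * n_pos`; the remaining cells follow.
#' Non-integer implied counts are rejected.
#'
#' @param sp_pct,se_pct printed specificity and sensitivity percentages
#' @param n_neg,n_pos class sizes of the test set
#' @return a `confusion_matrix`
#' @export
confusion_from_rates <- function(sp_pct, se_pct, n_neg, n_pos) {
  tn <- sp_pct / 100 * n_neg
  tp <- se_pct / 100 * n_pos
  if (abs(tn - round(tn)) > 1e-6 || abs(tp - round(tp)) > 1e-6)
    stop("rates are not consistent with integer counts at these class sizes")
  structure(list(TP = as.integer(round(tp)), TN = as.integer(round(tn)),
                 FP = n_neg - as.integer(round(tn)),
                 FN = n_pos - as.integer(round(tp))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP %d  FN %d\nFP %d  TN %d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Accuracy, specificity, sensitivity and precision of a confusion matrix
#'
#' Percentages are reported both raw and rounded half-up to two
#' decimals, the printing convention of the package's report tables.
#' Precision is `NA` (with a warning) when no slide was predicted
#' positive; the analogous guards apply to the other ratios.
#'
#' @param cm a [confusion()] result
#' @return object of class `metric_report`: `AC`, `SP`, `SE`, `PC`
#'   (rounded percentages), `raw` (unrounded), `counts`
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    100 * num / den
  }
  raw <- c(AC = safe(cm$TP + cm$TN, total, "accuracy"),
           SP = safe(cm$TN, cm$TN + cm$FP, "specificity"),
           SE = safe(cm$TP, cm$TP + cm$FN, "sensitivity"),
           PC = safe(cm$TP, cm$TP + cm$FP, "precision"))
  structure(list(AC = round_half_up(raw[["AC"]]),
                 SP = round_half_up(raw[["SP"]]),
                 SE = round_half_up(raw[["SE"]]),
                 PC = round_half_up(raw[["PC"]]),
                 raw = raw, counts = cm),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AC %.2f%%  SP %.2f%%  SE %.2f%%  PC %.2f%%\n",
              x$AC, x$SP, x$SE, x$PC))
  invisible(x)
}

#' Evaluate predictions into a per-slide table and a metric report
#'
#' @param predictions data.frame with `GT` and `PreCls` columns (as from
#'   [predict_nucmil()])
#' @return list with `table` (the input, unchanged) and `metrics`
#' @export
evaluate_predictions <- function(predictions) {
  cm <- confusion(predictions$GT, predictions$PreCls)
  list(table = predictions, metrics = classification_metrics(cm))
}
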