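#' Confusion counts between binary predictions and truth
#'
#' Works on binary masks (matrices) or label vectors; inputs must be
#' congruent and contain only 0/1 (or logical) values.
#'
#' @param pred,truth Binary masks or 0/1 vectors of identical shape.
#' @return List of class `fetalbiom_confusion` with integer `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth must have identical shape")
  p <- as.vector(pred); t <- as.vector(truth)
  if (!all(p %in% c(0, 1, TRUE, FALSE)) || !all(t %in% c(0, 1, TRUE, FALSE)))
    stop("pred and truth must be binary (0/1)")
  p <- as.logical(p); t <- as.logical(t)
  structure(list(
    tp = sum(p & t), tn = sum(!p & !t),
    fp = sum(p & !t), fn = sum(!p & t)
  ), class = "fetalbiom_confusion")
}

#' Segmentation / classification metric panel
#'
#' Computes accuracy, precision, recall, F1, Dice, specificity and
#' sensitivity from confusion counts:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = sensitivity = TP/(TP+FN), F1 = harmonic mean of precision and
#' recall, Dice = 2TP/(2TP+FP+FN), specificity = TN/(TN+FP).
#' A metric whose denominator is zero is reported as 0 and listed in
#' `degenerate`, keeping batch evaluation total.
#'
#' @param c Confusion counts from [confusion_counts()], or a list with
#'   fields `tp`, `tn`, `fp`, `fn`.
#' @return List of class `fetalbiom_metrics` with the seven metrics,
#'   `n_items`, and a character vector `degenerate`.
#' @export
#' @examples
#' metric_panel(list(tp = 3, tn = 5, fp = 1, fn = 1))
metric_panel <- function(c) {
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(c)))
  tp <- c$tp; tn <- c$tn; fp <- c$fp; fn <- c$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall    <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    degenerate <- c(degenerate, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  structure(list(
    accuracy    = safe(tp + tn, tp + tn + fp + fn, "accuracy"),
    precision   = precision,
    recall      = recall,
    f1          = f1,
    dice        = safe(2 * tp, 2 * tp + fp + fn, "dice"),
    specificity = safe(tn, tn + fp, "specificity"),
    sensitivity = recall,
    n_items     = tp + tn + fp + fn,
    degenerate  = degenerate
  ), class = "fetalbiom_metrics")
}

#' @export
print.fetalbiom_metrics <- function(x, ...) {
  cat(sprintf(paste0("metrics over %d items: accuracy %.4f | precision %.4f | ",
                     "recall %.4f | f1 %.4f | dice %.4f | specificity %.4f\n"),
              x$n_items, x$accuracy, x$precision, x$recall, x$f1, x$dice,
              x$specificity))
  if (length(x$degenerate))
    cat("  degenerate denominators:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Dice coefficient between two binary masks
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)}. When both masks are empty the score is
#' 1 by the perfect-agreement convention.
#'
#' @param a,b Binary masks of identical shape.
#' @return Dice overlap in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical shape")
  av <- as.vector(a); bv <- as.vector(b)
  if (!all(av %in% c(0, 1, TRUE, FALSE)) || !all(bv %in% c(0, 1, TRUE, FALSE)))
    stop("masks must be binary (0/1)")
  av <- as.logical(av); bv <- as.logical(bv)
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(1)
  2 * sum(av & bv) / (sa + sb)
}

#' Case-level expert-comparison metrics
#'
#' One-vs-rest binarization of predicted vs reference labels; by default the
#' positive class is "abnormal" (microcephaly or macrocephaly), matching a
#' screening reading where a miss is a false negative.
#'
#' @param pred_labels,true_labels Character vectors of labels among
#'   microcephaly / normal / macrocephaly.
#' @param positive Either `"abnormal"` (default) or one specific label.
#' @return `fetalbiom_metrics` panel over the cases.
#' @export
case_metric_panel <- function(pred_labels, true_labels, positive = "abnormal") {
  stopifnot(length(pred_labels) == length(true_labels))
  binarize <- function(l) {
    if (positive == "abnormal") l %in% c("microcephaly", "macrocephaly")
    else l == positive
  }
  metric_panel(confusion_counts(as.numeric(binarize(pred_labels)),
                                as.numeric(binarize(true_labels))))
}
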