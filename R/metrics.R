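## Per-class and global classification quality. All per-class measures are
## one-vs-rest; Sn/Sp/Pr are percentages, MCC lives in [-1, 1]. The global
## indices are the arithmetic means over classes: NER (non error rate) of
## the sensitivities, AvPr of the precisions.

new_confusion <- function(TP, FP, FN, TN, positive = NA_character_) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_("confusion counts must be non-negative integers")
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), TN = as.integer(TN),
                 positive = positive),
            class = "confusion")
}

#' One-vs-rest confusion matrix for a named class
#'
#' Tallies TP/FP/FN/TN counts treating `positive` as the positive class and
#' everything else as negative.
#'
#' @param y_true,y_pred aligned vectors of class labels.
#' @param positive the class treated as positive; must occur in the union of
#'   labels of `y_true` and `y_pred` levels.
#' @return an object of class `"confusion"` with integer fields
#'   `TP`, `FP`, `FN`, `TN`.
#' @examples
#' cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"), positive = "a")
#' unlist(cm[c("TP", "FP", "FN", "TN")])
#' @export
confusion_matrix <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred))
    stop_("y_true and y_pred must have the same length")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (!positive %in% c(y_true, y_pred))
    stop_("unknown class '%s'", positive)
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  new_confusion(tp, fp, fn, tn, positive = positive)
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("one-vs-rest confusion (positive: %s)\n", x$positive))
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              experimental = c("positive", "negative")))
  ## printed in the predicted x experimental layout
  print(t(m)[c(1, 2), ])
  invisible(x)
}

pct <- function(num, den) {
  if (den == 0) {
    warning("undefined measure: zero denominator", call. = FALSE)
    return(NA_real_)
  }
  100 * num / den
}

#' Primary per-class measures from a confusion matrix
#'
#' Sensitivity `100 * TP / (TP + FN)`, specificity `100 * TN / (TN + FP)`,
#' precision `100 * TP / (TP + FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A zero
#' denominator yields `NA` with a warning for the percentage measures and 0
#' for the MCC (the standard convention for a degenerate margin).
#'
#' @param cm a `"confusion"` object.
#' @return a single numeric value (percent for `sensitivity()`,
#'   `specificity()`, `precision()`; a value in `[-1, 1]` for `mcc()`).
#' @export
sensitivity <- function(cm) { stopifnot(inherits(cm, "confusion")); pct(cm$TP, cm$TP + cm$FN) }

#' @rdname sensitivity
#' @export
specificity <- function(cm) { stopifnot(inherits(cm, "confusion")); pct(cm$TN, cm$TN + cm$FP) }

#' @rdname sensitivity
#' @export
precision <- function(cm) { stopifnot(inherits(cm, "confusion")); pct(cm$TP, cm$TP + cm$FP) }

#' @rdname sensitivity
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  tp <- as.numeric(cm$TP); fp <- as.numeric(cm$FP)
  fn <- as.numeric(cm$FN); tn <- as.numeric(cm$TN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

report_from_cms <- function(cms) {
  classes <- names(cms)
  tab <- data.frame(
    class = classes,
    Sn = vapply(cms, sensitivity, numeric(1)),
    Sp = vapply(cms, specificity, numeric(1)),
    Pr = vapply(cms, precision, numeric(1)),
    MCC = vapply(cms, mcc, numeric(1)),
    row.names = NULL
  )
  n_eval <- cms[[1L]]$TP + cms[[1L]]$FP + cms[[1L]]$FN + cms[[1L]]$TN
  acc <- sum(vapply(cms, function(cm) cm$TP, integer(1))) / n_eval * 100
  if (anyNA(tab$Sn))
    warning("classes with undefined sensitivity excluded from NER",
            call. = FALSE)
  if (anyNA(tab$Pr))
    warning("classes with undefined precision excluded from AvPr",
            call. = FALSE)
  structure(list(per_class = tab,
                 NER = mean(tab$Sn, na.rm = TRUE),
                 AvPr = mean(tab$Pr, na.rm = TRUE),
                 accuracy = acc,
                 n = n_eval,
                 G = length(cms),
                 confusions = cms),
            class = "class_report")
}

#' Global multiclass evaluation report
#'
#' Builds per-class one-vs-rest confusion matrices and measures
#' (sensitivity, specificity, precision, MCC) plus the global indices
#' NER (mean sensitivity over classes) and AvPr (mean precision).
#' Overall accuracy is computed for reference but plays no role in model
#' selection, which relies on the class-balanced indices.
#'
#' @param y_true,y_pred aligned label vectors.
#' @param classes class set to evaluate; defaults to the levels of `y_true`
#'   (or its sorted unique values).
#' @return an object of class `"class_report"`: `per_class` data frame,
#'   `NER`, `AvPr`, `accuracy` (all percentages), `MCC` column in `[-1, 1]`,
#'   and the underlying confusion matrices.
#' @examples
#' r <- global_report(rep(c("a", "b", "c"), 4), rep(c("a", "b", "b"), 4))
#' r$NER
#' @export
global_report <- function(y_true, y_pred, classes = NULL) {
  if (is.null(classes))
    classes <- if (is.factor(y_true)) levels(y_true) else sort(unique(as.character(y_true)))
  if (length(classes) < 2L) stop_("at least two classes are required")
  yt <- as.character(y_true); yp <- as.character(y_pred)
  # with an explicit class set a class may be absent from both vectors:
  # all its counts then fall on the negative side
  cms <- lapply(classes, function(g)
    new_confusion(sum(yt == g & yp == g), sum(yt != g & yp == g),
                  sum(yt == g & yp != g), sum(yt != g & yp != g),
                  positive = g))
  names(cms) <- classes
  report_from_cms(cms)
}

#' Evaluation report from precomputed confusion matrices
#'
#' Computes the same per-class and global measures as [global_report()]
#' starting from one-vs-rest confusion matrices, e.g. matrices transcribed
#' from a publication.
#'
#' @param cms named list of `"confusion"` objects, one per class.
#' @return a `"class_report"` object.
#' @examples
#' rep <- report_from_confusions(validation_confusion_fixtures())
#' round(c(rep$NER, rep$AvPr), 2)
#' @export
report_from_confusions <- function(cms) {
  stopifnot(length(cms) >= 2L, all(vapply(cms, inherits, logical(1), "confusion")))
  if (is.null(names(cms)))
    names(cms) <- vapply(cms, function(cm) cm$positive, character(1))
  report_from_cms(cms)
}

#' Mean one-vs-rest Matthews correlation coefficient
#'
#' The multiclass MCC summary used as the model-selection currency: the
#' arithmetic mean of the per-class one-vs-rest MCCs.
#'
#' @inheritParams global_report
#' @return a value in `[-1, 1]`.
#' @export
mean_mcc <- function(y_true, y_pred, classes = NULL) {
  if (is.null(classes))
    classes <- if (is.factor(y_true)) levels(y_true)
               else sort(unique(as.character(y_true)))
  yt <- as.character(y_true); yp <- as.character(y_pred)
  mean(vapply(classes, function(g)
    mcc(new_confusion(sum(yt == g & yp == g), sum(yt != g & yp == g),
                      sum(yt == g & yp != g), sum(yt != g & yp != g),
                      positive = g)),
    numeric(1)))
}

#' @export
print.class_report <- function(x, digits = 1, ...) {
  cat(sprintf("multiclass report: %d classes, %d compounds\n", x$G, x$n))
  tab <- x$per_class
  tab$Sn <- round(tab$Sn, digits); tab$Sp <- round(tab$Sp, digits)
  tab$Pr <- round(tab$Pr, digits); tab$MCC <- round(tab$MCC, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("NER  %.2f%%   AvPr %.2f%%   accuracy %.2f%%\n",
              x$NER, x$AvPr, x$accuracy))
  invisible(x)
}

#' Serialize a class report
#'
#' Writes the per-class table and global indices as JSON, the layout used by
#' the pipeline artifacts.
#'
#' @param report a `"class_report"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report_json <- function(report, file) {
  stopifnot(inherits(report, "class_report"))
  jsonlite::write_json(
    list(per_class = report$per_class,
         NER = report$NER, AvPr = report$AvPr,
         accuracy = report$accuracy, n = report$n),
    file, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(file)
}
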