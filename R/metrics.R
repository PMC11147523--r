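# Confusion-matrix bookkeeping and the standard binary performance metrics
# (accuracy, sensitivity, specificity, precision, MCC, error rate, F1),
# with undefined (zero-denominator) metrics surfaced as NA, never as 0.

#' Tally a binary confusion matrix
#'
#' Partitions `(y_true, y_pred)` pairs against a designated positive label
#' into true/false positives and negatives.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param positive_label the label treated as the positive class.
#' @return an object of class `confusion_counts`: a list with integer fields
#'   `tp`, `tn`, `fp`, `fn` summing to `length(y_true)`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0), positive_label = 1)
#' @export
confusion_counts <- function(y_true, y_pred, positive_label) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  tr <- y_true == positive_label
  pr <- y_pred == positive_label
  out <- list(
    tp = sum(tr & pr), tn = sum(!tr & !pr),
    fp = sum(!tr & pr), fn = sum(tr & !pr)
  )
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: tp=%d tn=%d fp=%d fn=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity (recall), specificity, precision, Matthews
#' correlation coefficient, error rate and F1 score. Any metric whose
#' denominator is zero is reported as `NA` (flagged undefined) rather than 0,
#' so degenerate one-class inputs never silently inflate averages.
#'
#' The error rate has two conventions: `complement_accuracy` (`1 - ACC`,
#' the default, which matches the fused classifier's reported error rates)
#' and `balanced` (`1 - (SEN + SPC)/2`).
#'
#' @param counts a `confusion_counts` object (or list with tp/tn/fp/fn).
#' @param er_mode `"complement_accuracy"` or `"balanced"`.
#' @param scale `"fraction"` (canonical) or `"percent"` (acc/sen/spc/pre/err/f1
#'   multiplied by 100; mcc is a correlation and is left unscaled).
#' @return an object of class `metric_set`: named numeric vector with fields
#'   `acc`, `sen`, `spc`, `pre`, `mcc`, `err`, `f1` and a `scale` attribute.
#' @export
classification_metrics <- function(counts,
                                   er_mode = c("complement_accuracy", "balanced"),
                                   scale = c("fraction", "percent")) {
  er_mode <- match.arg(er_mode)
  scale <- match.arg(scale)
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  n <- tp + tn + fp + fn
  if (n < 1) stop("no observations")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- (tp + tn) / n
  sen <- safe_div(tp, tp + fn)
  spc <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  mcc_den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mcc_den)
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_ else
    2 * pre * sen / (pre + sen)
  err <- if (er_mode == "complement_accuracy") 1 - acc else {
    if (is.na(sen) || is.na(spc)) NA_real_ else 1 - (sen + spc) / 2
  }
  m <- c(acc = acc, sen = sen, spc = spc, pre = pre, mcc = mcc, err = err, f1 = f1)
  if (scale == "percent") {
    pct <- c("acc", "sen", "spc", "pre", "err", "f1")
    m[pct] <- 100 * m[pct]
  }
  structure(m, scale = scale, er_mode = er_mode, class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  cat(sprintf("metric set (%s scale):\n", attr(x, "scale")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' One-vs-rest metric report for multi-class predictions
#'
#' Binarizes a multi-class problem per class (class vs rest), computes a
#' [classification_metrics()] row for each, and appends a macro-average row
#' (mean of the per-class values, `NA`s removed per column).
#'
#' @inheritParams confusion_counts
#' @inheritParams classification_metrics
#' @return a data.frame with one row per class plus a `"macro"` row and
#'   columns `class, acc, sen, spc, pre, mcc, err, f1`.
#' @export
one_vs_rest_report <- function(y_true, y_pred,
                               er_mode = c("complement_accuracy", "balanced"),
                               scale = c("fraction", "percent")) {
  er_mode <- match.arg(er_mode)
  scale <- match.arg(scale)
  classes <- sort(unique(as.character(y_true)))
  if (length(classes) < 2) stop("one_vs_rest_report needs >= 2 classes in y_true")
  rows <- lapply(classes, function(cl) {
    m <- classification_metrics(confusion_counts(as.character(y_true),
                                                 as.character(y_pred), cl),
                                er_mode = er_mode, scale = scale)
    as.data.frame(as.list(unclass(m)))
  })
  rep <- do.call(rbind, rows)
  macro <- colMeans(rep, na.rm = TRUE)
  rep <- rbind(rep, macro)
  data.frame(class = c(classes, "macro"), rep, row.names = NULL)
}

#' Write a metric report to JSON or CSV
#'
#' JSON output nests `class -> metric -> value`; CSV output has one row per
#' class with columns `class, acc, ..., f1`.
#'
#' @param report a data.frame from [one_vs_rest_report()].
#' @param path output file; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    lst <- lapply(seq_len(nrow(report)), function(i)
      as.list(report[i, setdiff(names(report), "class"), drop = FALSE]))
    names(lst) <- report$class
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else if (ext == "csv") {
    utils::write.csv(report, path, row.names = FALSE)
  } else stop("unsupported report format: ", ext)
  invisible(path)
}
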