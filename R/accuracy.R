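#' Classification accuracy from a 2x2 contingency table
#'
#' Operating characteristics of a binary classifier against true case
#' status: sensitivity, specificity, predictive values, likelihood ratios.
#' Internal values are kept at full precision; rounding to one decimal (as
#' in the published validation tables) happens only in the formatter.
#'
#' @param tp,fp,fn,tn nonnegative counts.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) stop_spec("contingency cells must be nonnegative")
  if (sum(cells) <= 0) stop_spec("contingency table is empty")
  structure(as.list(cells), class = "contingency_table")
}

#' Cross-tabulate an assignment vector against truth
#' @param truth,assigned logical vectors of equal length.
#' @export
contingency_from_assignment <- function(truth, assigned) {
  stopifnot(length(truth) == length(assigned))
  contingency_table(tp = sum(assigned & truth), fp = sum(assigned & !truth),
                    fn = sum(!assigned & truth), tn = sum(!assigned & !truth))
}

#' @rdname contingency_table
#' @param t a `contingency_table`.
#' @return `compute_accuracy()`: object of class `accuracy_stats` with
#'   sensitivity, specificity, ppv, npv, plr (`Inf` when fp = 0), nlr, and
#'   `ppv_defined` (FALSE when no positives were called).
#' @export
compute_accuracy <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$tp + t$fn == 0) stop_degenerate("empty positive margin (tp + fn = 0)")
  if (t$fp + t$tn == 0) stop_degenerate("empty negative margin (fp + tn = 0)")
  sens <- t$tp / (t$tp + t$fn)
  spec <- t$tn / (t$fp + t$tn)
  ppv_defined <- (t$tp + t$fp) > 0
  ppv <- if (ppv_defined) t$tp / (t$tp + t$fp) else NA_real_
  npv <- if (t$fn + t$tn > 0) t$tn / (t$fn + t$tn) else NA_real_
  plr <- if (t$fp == 0) Inf else sens / (1 - spec)
  nlr <- if (spec > 0) (1 - sens) / spec else NA_real_
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, plr = plr, nlr = nlr, ppv_defined = ppv_defined,
                 table = t),
            class = "accuracy_stats")
}

#' Format accuracy statistics the way validation tables print them
#'
#' Percentages and likelihood ratios rounded to one decimal place.
#' @param x an `accuracy_stats`.
#' @param label optional classifier label.
#' @return character vector of report lines.
#' @export
format_accuracy <- function(x, label = "classifier") {
  stopifnot(inherits(x, "accuracy_stats"))
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  lr <- function(v) if (is.infinite(v)) "Inf" else sprintf("%.1f", v)
  t <- x$table
  c(sprintf("%s: TP=%d FP=%d FN=%d TN=%d", label, t$tp, t$fp, t$fn, t$tn),
    sprintf("  Sens %s  Spec %s  +PV %s  -PV %s  +LR %s  -LR %s",
            pct(x$sensitivity), pct(x$specificity), pct(x$ppv), pct(x$npv),
            lr(x$plr), lr(x$nlr)))
}

#' @export
print.accuracy_stats <- function(x, ...) {
  cat(format_accuracy(x), sep = "\n")
  invisible(x)
}

#' Reference contingency tables from the validation cohort
#'
#' The four published 2x2 tables cross-tabulating assigned against true
#' cystectomy-diversion status in the 428,697-admission cohort the
#' simulator emulates: procedure-code assignment and model-threshold
#' assignment, for each diversion type. Shipped as plain-text package data;
#' used by the acceptance report to reproduce the printed operating
#' characteristics.
#'
#' @return data.frame with columns classifier, diversion, tp, fp, fn, tn.
#' @export
reference_accuracy_counts <- function() {
  path <- system.file("extdata", "reference_code_counts.csv",
                      package = "cystmisclass", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
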