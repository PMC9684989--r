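## Diagnostic-accuracy validation ---------------------------------------------

#' One-vs-rest confusion counts for a single label
#'
#' @param truths Character vector of ground-truth labels.
#' @param predictions Character vector of predicted labels (same length).
#' @param label The positive class.
#' @return List with `label`, `tp`, `fp`, `tn`, `fn` (summing to the cohort
#'   size).
#' @export
confusion_counts <- function(truths, predictions, label) {
  if (length(truths) != length(predictions)) {
    stop("truths and predictions differ in length (",
         length(truths), " vs ", length(predictions), ")")
  }
  if (length(truths) == 0) stop("empty input")
  pos_t <- truths == label
  pos_p <- predictions == label
  list(label = label,
       tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
       tn = sum(!pos_t & !pos_p), fn = sum(pos_t & !pos_p))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, from the beta-quantile
#' closed form; at the boundaries it reduces to
#' `lower = (alpha/2)^(1/n)` when all trials succeed and
#' `upper = 1 - (alpha/2)^(1/n)` when none do.
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (>= 1; 0 returns `NA` bounds).
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` of proportions.
#' @export
clopper_pearson_ci <- function(successes, trials, confidence = 0.95) {
  stopifnot(confidence > 0, confidence < 1)
  if (trials == 0) return(c(lower = NA_real_, upper = NA_real_))
  stopifnot(successes >= 0, successes <= trials)
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else {
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  }
  upper <- if (successes == trials) 1 else {
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  }
  c(lower = lower, upper = upper)
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metrics from one-vs-rest confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), NPV
#' tn/(tn+fn), prevalence (tp+fn)/N, accuracy (tp+tn)/N, and balanced
#' accuracy (mean of sensitivity and specificity). Any ratio with a zero
#' denominator is `NA` (e.g. sensitivity of a disease absent from the
#' cohort). Sensitivity and specificity carry exact 95% (by default)
#' Clopper-Pearson intervals.
#'
#' @param counts Output of [confusion_counts()].
#' @param confidence Confidence level for the exact intervals.
#' @return List of metrics (proportions in `[0, 1]`) and `sensitivity_ci` /
#'   `specificity_ci` bounds.
#' @export
diagnostic_metrics <- function(counts, confidence = 0.95) {
  with(counts, {
    n <- tp + fp + tn + fn
    sens <- ratio_or_na(tp, tp + fn)
    spec <- ratio_or_na(tn, tn + fp)
    list(
      label = label, tp = tp, fp = fp, tn = tn, fn = fn,
      prevalence = ratio_or_na(tp + fn, n),
      sensitivity = sens,
      sensitivity_ci = if (tp + fn > 0) {
        clopper_pearson_ci(tp, tp + fn, confidence)
      } else c(lower = NA_real_, upper = NA_real_),
      specificity = spec,
      specificity_ci = if (tn + fp > 0) {
        clopper_pearson_ci(tn, tn + fp, confidence)
      } else c(lower = NA_real_, upper = NA_real_),
      ppv = ratio_or_na(tp, tp + fp),
      npv = ratio_or_na(tn, tn + fn),
      accuracy = ratio_or_na(tp + tn, n),
      balanced_accuracy = if (is.na(sens) || is.na(spec)) {
        NA_real_
      } else (sens + spec) / 2)
  })
}

#' Full validation report (one row per label plus a malignancy row)
#'
#' Computes one-vs-rest [diagnostic_metrics()] for each requested disease
#' label and, when malignancy flags are supplied, a `"Malignancy"` row
#' treating any flag other than `NONE` as positive regardless of subtype.
#'
#' @param truths Ground-truth disease labels.
#' @param predictions Predicted disease labels.
#' @param labels Disease labels to report (default [disease_labels()]).
#' @param true_malignancy,predicted_malignancy Optional malignancy flag
#'   vectors (`NONE` / `SCAR_CARCINOMA` / `METASTASIS`).
#' @param confidence Confidence level for the exact intervals.
#' @return Data.frame, one row per label, with confusion counts, metrics and
#'   CI bounds (`sensitivity_lo/hi`, `specificity_lo/hi`).
#' @export
validation_report <- function(truths, predictions,
                              labels = disease_labels(),
                              true_malignancy = NULL,
                              predicted_malignancy = NULL,
                              confidence = 0.95) {
  one_row <- function(m) {
    data.frame(label = m$label, tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
               prevalence = m$prevalence,
               sensitivity = m$sensitivity,
               sensitivity_lo = m$sensitivity_ci[["lower"]],
               sensitivity_hi = m$sensitivity_ci[["upper"]],
               specificity = m$specificity,
               specificity_lo = m$specificity_ci[["lower"]],
               specificity_hi = m$specificity_ci[["upper"]],
               ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
               balanced_accuracy = m$balanced_accuracy,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(labels, function(lab) {
    one_row(diagnostic_metrics(confusion_counts(truths, predictions, lab),
                               confidence))
  })
  if (!is.null(true_malignancy) && !is.null(predicted_malignancy)) {
    cc <- confusion_counts(ifelse(true_malignancy == "NONE" |
                                    is.na(true_malignancy),
                                  "negative", "positive"),
                           ifelse(predicted_malignancy == "NONE",
                                  "negative", "positive"),
                           "positive")
    cc$label <- "Malignancy"
    rows <- c(rows, list(one_row(diagnostic_metrics(cc, confidence))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a validation report as percentages
#'
#' Formats proportions to one decimal percent and balanced accuracy to three
#' decimals, mirroring the study's reporting style; `NA` prints as `"NA"`.
#'
#' @param report Output of [validation_report()].
#' @return Character data.frame for printing/writing.
#' @export
format_validation_report <- function(report) {
  pct <- function(x) ifelse(is.na(x), "NA",
                            paste0(formatC(100 * x, format = "f",
                                           digits = 1), "%"))
  data.frame(
    label = report$label,
    tp = report$tp, fp = report$fp, tn = report$tn, fn = report$fn,
    prevalence = pct(report$prevalence),
    sensitivity = pct(report$sensitivity),
    sensitivity_95ci = ifelse(is.na(report$sensitivity), "NA",
                              paste0(pct(report$sensitivity_lo), " to ",
                                     pct(report$sensitivity_hi))),
    specificity = pct(report$specificity),
    specificity_95ci = ifelse(is.na(report$specificity), "NA",
                              paste0(pct(report$specificity_lo), " to ",
                                     pct(report$specificity_hi))),
    ppv = pct(report$ppv), npv = pct(report$npv),
    accuracy = pct(report$accuracy),
    balanced_accuracy = ifelse(is.na(report$balanced_accuracy), "NA",
                               formatC(report$balanced_accuracy,
                                       format = "f", digits = 3)),
    stringsAsFactors = FALSE)
}
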