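## Feature prevalence and one-vs-rest chi-square significance -----------------

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Computes the Pearson statistic from the closed form
#' \deqn{X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' with an optional Yates continuity adjustment replacing \eqn{|ad - bc|} by
#' \eqn{\max(0, |ad - bc| - N/2)}; the p-value comes from the chi-square
#' distribution with one degree of freedom. A table with a zero margin has no
#' defined association test and returns `NA` for both components rather than
#' raising.
#'
#' @param a,b,c,d Non-negative cell counts (a = feature & disease,
#'   b = feature & other disease, c = no feature & disease, d = neither).
#' @param correction `"none"` (Pearson, default) or `"yates"`.
#' @return List with elements `statistic` and `p_value` (both `NA` when a
#'   margin is zero).
#' @export
chi_square_2x2 <- function(a, b, c, d, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  dev <- abs(a * d - b * c)
  if (correction == "yates") dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

check_labeled <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort")
  unl <- which(is.na(cohort$true_label))
  if (length(unl) > 0) {
    stop("unlabeled record(s): ",
         paste(cohort$patient_id[unl], collapse = ", "))
  }
  if (length(unique(cohort$true_label)) < 2) {
    stop("cohort must cover at least two diseases")
  }
}

feature_positive <- function(cohort, feature) {
  x <- cohort[[feature]]
  if (is.logical(x)) x else x == "true"
}

#' Features entering the prevalence/significance analysis
#'
#' All boolean clinical/imaging fields plus the tri-state laboratory and MRI
#' fields (counting explicit positive results only).
#'
#' @return Character vector of feature names.
#' @export
significance_features <- function() {
  c(boolean_fields(), tristate_fields())
}

#' Per-disease feature prevalence table
#'
#' For each (disease, feature) pair, counts the patients of that disease with
#' the feature present. Tri-state features count only explicit `"true"`
#' results, but the denominator is always the disease's full patient count
#' (an unperformed test neither adds to the numerator nor shrinks the
#' denominator), matching the published table's convention.
#'
#' @param cohort Labeled cohort (every record has `true_label`).
#' @param features Feature names (default [significance_features()]).
#' @return Data.frame with columns `disease`, `feature`, `count`, `n_disease`
#'   and `percent` (rounded to one decimal).
#' @export
prevalence_table <- function(cohort, features = significance_features()) {
  check_labeled(cohort)
  diseases <- intersect(disease_labels(), unique(cohort$true_label))
  rows <- expand.grid(disease = diseases, feature = features,
                      stringsAsFactors = FALSE)[, c("disease", "feature")]
  rows <- rows[order(match(rows$disease, diseases),
                     match(rows$feature, features)), ]
  n_dis <- table(factor(cohort$true_label, levels = diseases))
  rows$count <- mapply(function(d, f) {
    sum(feature_positive(cohort, f) & cohort$true_label == d)
  }, rows$disease, rows$feature)
  rows$n_disease <- as.integer(n_dis[rows$disease])
  rows$percent <- round(100 * rows$count / rows$n_disease, 1)
  rownames(rows) <- NULL
  rows
}

#' One-vs-rest chi-square significance table
#'
#' Extends [prevalence_table()] with an association test per cell: for each
#' (disease, feature) the 2x2 table is feature-vs-not crossed with
#' disease-vs-all-others over the whole cohort. A cell is reported
#' `not_applicable` (`NA` p-value) when the test was never performed for that
#' disease (every patient of the disease has the tri-state feature
#' `not_done`) or when the 2x2 table has a zero margin (feature constant
#' across the cohort).
#'
#' @inheritParams prevalence_table
#' @param correction Passed to [chi_square_2x2()].
#' @param adjust Optional multiple-testing adjustment applied across all
#'   tested cells (a `stats::p.adjust` method, e.g. `"bonferroni"` or
#'   `"BH"`); `"none"` (default) matches the original single-test analysis.
#' @return The prevalence data.frame with added columns `statistic`,
#'   `p_value` and `significant` (p < 0.05; `NA` when not applicable).
#' @export
significance_table <- function(cohort, features = significance_features(),
                               correction = c("none", "yates"),
                               adjust = "none") {
  correction <- match.arg(correction)
  tab <- prevalence_table(cohort, features)
  n <- nrow(cohort)
  res <- mapply(function(d, f) {
    x <- feature_positive(cohort, f)
    in_dis <- cohort$true_label == d
    if (f %in% tristate_fields() &&
        all(cohort[[f]][in_dis] == "not_done")) {
      return(c(NA_real_, NA_real_))
    }
    a <- sum(x & in_dis); b <- sum(x & !in_dis)
    cc <- sum(!x & in_dis); dd <- sum(!x & !in_dis)
    t <- chi_square_2x2(a, b, cc, dd, correction)
    c(t$statistic, t$p_value)
  }, tab$disease, tab$feature)
  tab$statistic <- res[1, ]
  tab$p_value <- res[2, ]
  if (adjust != "none") {
    tab$p_value <- stats::p.adjust(tab$p_value, method = adjust)
  }
  tab$significant <- tab$p_value < 0.05
  tab
}

#' Render a p-value the way the study reports it
#'
#' Three decimals with a `"< 0.001"` floor; `"N/A"` for untestable cells.
#'
#' @param p Numeric vector of p-values (may contain `NA`).
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  out <- ifelse(is.na(p), "N/A",
                ifelse(p < 0.001, "< 0.001",
                       formatC(round(p, 3), format = "g")))
  out
}
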