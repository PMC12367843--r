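# Descriptive group comparisons: two-tailed heteroscedastic (Welch) t-tests
# for continuous measurements and Pearson chi-squared tests (no continuity
# correction, matching common spreadsheet behaviour) for discrete ones.
# No multiple-testing adjustment is applied; alpha = 0.05 throughout.

#' Welch two-sample t-test
#'
#' Two-tailed heteroscedastic t-test with Welch-Satterthwaite degrees of
#' freedom, returned as a one-row comparison table.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param variable Label for the compared variable.
#' @return A one-row tibble with `variable`, `test`, `statistic`, `df`,
#'   `p_value`.
#' @export
welch_t_test <- function(a, b, variable = "value") {
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least two observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate comparison: zero variance in both samples",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(variable = variable, test = "welch_t",
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction,
#' `df = (rows - 1) * (cols - 1)`.  All expected counts must be positive.
#'
#' @param table A matrix (or coercible) of counts, e.g. 2 x k.
#' @param variable Label for the compared variable.
#' @return A one-row tibble with `variable`, `test`, `statistic`, `df`,
#'   `p_value`.
#' @export
chi_squared_test <- function(table, variable = "counts") {
  m <- as.matrix(table)
  stopifnot(all(m >= 0), nrow(m) >= 2, ncol(m) >= 2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected <= 0) || any(!is.finite(expected))) {
    stop("zero expected cell count", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(variable = variable, test = "chi_squared",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value)
}
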