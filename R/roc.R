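# ROC discrimination and likelihood ratios.
#
# Orientation convention: rupture is associated with LOWER values of the
# WTR family, so "lower_is_ruptured" indices are negated internally before
# any AUC computation, making AUC > 0.5 comparable across indices.  At a
# cutoff, the positive (rupture) call is score <= cutoff for
# lower_is_ruptured and score >= cutoff for higher_is_ruptured.

roc_orientations <- c("higher_is_ruptured", "lower_is_ruptured")

orient_scores <- function(scores, orientation) {
  orientation <- match.arg(orientation, roc_orientations)
  if (orientation == "lower_is_ruptured") -scores else scores
}

positive_calls <- function(scores, cutoff, orientation) {
  orientation <- match.arg(orientation, roc_orientations)
  if (orientation == "lower_is_ruptured") scores <= cutoff else scores >= cutoff
}

#' Area under the ROC curve by midranks
#'
#' The Mann-Whitney probability estimate `P(score_case > score_control)`
#' with ties counted one half, computed from midranks; identical to the
#' trapezoidal area under the empirical ROC curve.  Scores must already be
#' oriented so that higher values indicate rupture.
#'
#' @param scores Numeric scores, oriented higher = ruptured.
#' @param labels Logical (or 0/1) rupture status.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_midrank(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)) # 1
#' @export
auc_midrank <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores) # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confidence interval for the AUC
#'
#' 95% (by default) interval via the DeLong nonparametric covariance
#' estimate, or via a stratified bootstrap for sensitivity analysis.  The
#' interval is clipped to `[0, 1]`.  Bootstrap resampling uses the current
#' RNG state, so seed beforehand for reproducibility.
#'
#' @param scores Numeric index values (raw, not pre-oriented).
#' @param labels Logical rupture status.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param orientation See [roc_analysis()].
#' @param boot_n Bootstrap resamples (default 2000).
#' @param conf Confidence level.
#' @return Named numeric `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   orientation = "higher_is_ruptured", boot_n = 2000,
                   conf = 0.95) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2) {
    stop("AUC confidence interval needs at least two observations per class",
         call. = FALSE)
  }
  oriented <- orient_scores(scores, orientation)
  rr <- pROC::roc(response = labels, predictor = oriented,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- if (method == "delong") {
    pROC::ci.auc(rr, conf.level = conf, method = "delong")
  } else {
    pROC::ci.auc(rr, conf.level = conf, method = "bootstrap",
                 boot.n = boot_n, boot.stratified = TRUE)
  }
  c(low = max(0, as.numeric(ci[1])), high = min(1, as.numeric(ci[3])))
}

#' Sensitivity and specificity at a cutoff
#'
#' For `lower_is_ruptured`, a score at or below the cutoff is called
#' positive (ruptured); for `higher_is_ruptured`, at or above.
#'
#' @inheritParams auc_ci
#' @param cutoff Index value at which to dichotomise.
#' @return Named numeric `c(sensitivity, specificity)`.
#' @export
sens_spec_at_cutoff <- function(scores, labels, cutoff,
                                orientation = "higher_is_ruptured") {
  labels <- as.logical(labels)
  pos <- positive_calls(scores, cutoff, orientation)
  c(sensitivity = mean(pos[labels]), specificity = mean(!pos[!labels]))
}

#' Youden-optimal cutoff
#'
#' Returns the cutoff maximising Youden's J = sensitivity + specificity - 1
#' over the observed score values.  Ties are broken toward the cutoff with
#' higher sensitivity, then toward the smaller cutoff.  When the optimal
#' observed value has a neighbouring observed value on the negative side of
#' the call, the midpoint of the gap is returned (the conventional reported
#' threshold); with a single distinct score the value itself is returned.
#'
#' @inheritParams auc_ci
#' @return A single cutoff value.
#' @export
youden_cutoff <- function(scores, labels, orientation = "higher_is_ruptured") {
  orientation <- match.arg(orientation, roc_orientations)
  labels <- as.logical(labels)
  if (sum(labels) == 0 || sum(!labels) == 0) {
    stop("both classes must be present to choose a cutoff", call. = FALSE)
  }
  cand <- sort(unique(scores))
  ss <- vapply(cand, function(cc) {
    sens_spec_at_cutoff(scores, labels, cc, orientation)
  }, numeric(2))
  j <- ss[1, ] + ss[2, ] - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[ss[1, best] == max(ss[1, best])]
  best <- min(best) # smaller cutoff on remaining ties
  v <- cand[best]
  if (orientation == "lower_is_ruptured") {
    if (best < length(cand)) (v + cand[best + 1]) / 2 else v
  } else {
    if (best > 1) (v + cand[best - 1]) / 2 else v
  }
}

#' Positive likelihood ratio
#'
#' `LR+ = sensitivity / (1 - specificity)`: the factor by which a positive
#' call multiplies the odds of rupture status.  A specificity of 1 yields
#' an infinite LR, returned as `Inf` with a warning rather than an error.
#'
#' @param sens Sensitivity (proportion).
#' @param spec Specificity (proportion).
#' @return Dimensionless likelihood ratio.
#' @examples
#' positive_lr(23 / 28, 32 / 52) # 2.14 as printed
#' @export
positive_lr <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  if (spec >= 1) {
    warning("specificity of 1 gives an infinite positive likelihood ratio")
    return(Inf)
  }
  sens / (1 - spec)
}

#' Confidence interval for the positive likelihood ratio
#'
#' Log-method interval (Simel): `exp(log(LR) +/- z * se)` with
#' `se^2 = (1 - sens)/tp + spec/fp`.  If any confusion cell is zero, a 0.5
#' continuity correction is added to every cell; the result then carries
#' attribute `continuity_corrected = TRUE`.
#'
#' @param tp,fn,tn,fp Confusion counts (true/false positives/negatives for
#'   the rupture call).
#' @param conf Confidence level, default 0.95.
#' @return Named numeric `c(low, high)`; attribute `continuity_corrected`.
#' @export
lr_ci <- function(tp, fn, tn, fp, conf = 0.95) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  stopifnot(all(counts >= 0), tp + fn > 0, tn + fp > 0)
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  sens <- counts["tp"] / (counts["tp"] + counts["fn"])
  spec <- counts["tn"] / (counts["tn"] + counts["fp"])
  lr <- sens / (1 - spec)
  se <- sqrt((1 - sens) / counts["tp"] + spec / counts["fp"])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- c(low = unname(exp(log(lr) - z * se)),
           high = unname(exp(log(lr) + z * se)))
  attr(out, "continuity_corrected") <- corrected
  out
}

#' Empirical ROC points
#'
#' Sensitivity and specificity at every distinct observed score value,
#' using the orientation's inclusive call rule.
#'
#' @inheritParams auc_ci
#' @return A tibble with columns `cutoff`, `sens`, `spec`.
#' @export
roc_points <- function(scores, labels, orientation = "higher_is_ruptured") {
  cuts <- sort(unique(scores))
  ss <- vapply(cuts, function(cc) {
    sens_spec_at_cutoff(scores, labels, cc, orientation)
  }, numeric(2))
  tibble::tibble(cutoff = cuts, sens = ss[1, ], spec = ss[2, ])
}

#' Full ROC analysis of one index
#'
#' Bundles the oriented AUC with its confidence interval, the empirical ROC
#' points, a cutoff (user-supplied, else Youden-optimal), the sensitivity,
#' specificity and positive likelihood ratio at that cutoff, and the LR
#' confidence interval.
#'
#' @inheritParams auc_ci
#' @param index_name Label for the index analysed.
#' @param cutoff Optional cutoff to evaluate; if `NULL` the Youden-optimal
#'   cutoff is chosen.
#' @param ci_method AUC interval method, `"delong"` or `"bootstrap"`.
#' @return An object of class `roc_analysis`.
#' @export
roc_analysis <- function(scores, labels, index_name = "index",
                         orientation = c("higher_is_ruptured",
                                         "lower_is_ruptured"),
                         cutoff = NULL, ci_method = "delong", boot_n = 2000) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  oriented <- orient_scores(scores, orientation)
  auc <- auc_midrank(oriented, labels)
  ci <- auc_ci(scores, labels, method = ci_method, orientation = orientation,
               boot_n = boot_n)
  pts <- roc_points(scores, labels, orientation)
  if (is.null(cutoff)) cutoff <- youden_cutoff(scores, labels, orientation)
  ss <- sens_spec_at_cutoff(scores, labels, cutoff, orientation)
  pos <- positive_calls(scores, cutoff, orientation)
  tp <- sum(pos & labels); fn <- sum(!pos & labels)
  tn <- sum(!pos & !labels); fp <- sum(pos & !labels)
  lr <- if (ss[["specificity"]] >= 1) Inf else {
    positive_lr(ss[["sensitivity"]], ss[["specificity"]])
  }
  lrci <- lr_ci(tp, fn, tn, fp)
  structure(list(index_name = index_name, orientation = orientation,
                 points = pts, auc = auc, auc_ci = ci,
                 chosen_cutoff = cutoff,
                 sens = ss[["sensitivity"]], spec = ss[["specificity"]],
                 positive_lr = lr, lr_ci = lrci,
                 counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 n = length(scores)),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat("ROC analysis of ", x$index_name, " (", x$orientation, ", n = ", x$n,
      ")\n", sep = "")
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci[["low"]], x$auc_ci[["high"]]))
  cat(sprintf("  cutoff %.4g: sens %.1f%%, spec %.1f%%, LR+ %.3g (95%% CI %.3g-%.3g)\n",
              x$chosen_cutoff, 100 * x$sens, 100 * x$spec,
              x$positive_lr, x$lr_ci[["low"]], x$lr_ci[["high"]]))
  invisible(x)
}
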