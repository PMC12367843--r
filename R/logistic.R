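# Single-predictor binary logistic regression with critical-value
# inversion.  Convention: the linear predictor is eta = beta0 + beta1 * x,
# P(ruptured | x) = 1 / (1 + exp(-eta)).  The published all-site model for
# WTR is beta0 = 0.577, beta1 = -72.8 (rupture probability decreases with
# WTR), whose P = 0.5 crossing is the critical value -beta0/beta1.

#' Construct a logistic model from known coefficients
#'
#' Useful for evaluating published fits (critical values, odds ratios,
#' predicted probabilities) without refitting.
#'
#' @param beta0 Intercept (log-odds at index value 0).
#' @param beta1 Slope (log-odds change per unit index).
#' @param index_name Label of the predictor index.
#' @return An object of class `logistic_model`.
#' @examples
#' critical_value(logistic_model(0.577, -72.8)) # 7.93e-3
#' @export
logistic_model <- function(beta0, beta1, index_name = "index") {
  stopifnot(is.numeric(beta0), length(beta0) == 1, is.finite(beta0),
            is.numeric(beta1), length(beta1) == 1, is.finite(beta1))
  structure(list(index_name = index_name, beta0 = beta0, beta1 = beta1,
                 se_beta0 = NA_real_, se_beta1 = NA_real_,
                 p_value = NA_real_, converged = NA, n_iter = NA_integer_,
                 n = NA_integer_),
            class = "logistic_model")
}

#' Fit a single-predictor logistic regression by IRLS
#'
#' Maximum-likelihood intercept and slope via iteratively reweighted least
#' squares; convergence is declared when the largest absolute coefficient
#' change falls below `tol` (default 1e-8) within `max_iter` iterations.
#' Perfect separation is detected (disjoint class supports, or coefficient
#' divergence beyond 1e3 in magnitude) and raised as an error, as is
#' non-convergence.  The slope p-value is a two-sided Wald test.
#'
#' @param x Numeric predictor (index values).
#' @param y Logical (or 0/1) rupture status.
#' @param index_name Label of the predictor.
#' @param tol Convergence tolerance on coefficients.
#' @param max_iter Maximum IRLS iterations.
#' @return A `logistic_model` with standard errors, Wald p-value,
#'   convergence flag and iteration count.
#' @export
fit_logistic <- function(x, y, index_name = "index", tol = 1e-8,
                         max_iter = 100L) {
  y <- as.numeric(as.logical(y))
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (max(x[y == 1]) < min(x[y == 0]) || min(x[y == 1]) > max(x[y == 0])) {
    stop("perfect separation: the classes have disjoint predictor ranges",
         call. = FALSE)
  }
  X <- cbind(1, x)
  beta <- c(0, 0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / wts
    XtW <- t(X * wts)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (max(abs(beta)) > 1e3) {
      stop("perfect separation: coefficients diverging (|beta| > 1e3 at ",
           "iteration ", it, ")", call. = FALSE)
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("IRLS did not converge within ", max_iter, " iterations",
         call. = FALSE)
  }
  beta <- unname(beta)
  mu <- stats::plogis(drop(X %*% beta))
  wts <- pmax(mu * (1 - mu), 1e-12)
  vcov <- solve(t(X * wts) %*% X)
  se <- unname(sqrt(diag(vcov)))
  zstat <- beta[2] / se[2]
  structure(list(index_name = index_name, beta0 = beta[1], beta1 = beta[2],
                 se_beta0 = se[1], se_beta1 = se[2],
                 p_value = 2 * stats::pnorm(-abs(zstat)),
                 converged = TRUE, n_iter = it, n = length(y)),
            class = "logistic_model")
}

#' Predicted rupture probability
#'
#' @param object A `logistic_model`.
#' @param x Index values at which to predict.
#' @param ... Unused.
#' @return Probabilities `1 / (1 + exp(-(beta0 + beta1 * x)))`.
#' @export
predict.logistic_model <- function(object, x, ...) {
  stats::plogis(object$beta0 + object$beta1 * x)
}

#' Critical index value of a logistic model
#'
#' The index value at which the fitted probability of presenting as
#' ruptured equals `p`: `(logit(p) - beta0) / beta1`, which for p = 0.5 is
#' `-beta0 / beta1`.  This is the quantity compared against the
#' theoretical thin-shell rupture threshold.
#'
#' @param model A `logistic_model`.
#' @param p Target probability, default 0.5.
#' @return The critical index value.
#' @examples
#' critical_value(logistic_model(0.577, -72.8)) # prints as 7.9e-3
#' @export
critical_value <- function(model, p = 0.5) {
  stopifnot(p > 0, p < 1)
  if (model$beta1 == 0) {
    stop("no crossing: the logistic slope is zero", call. = FALSE)
  }
  (stats::qlogis(p) - model$beta0) / model$beta1
}

#' Odds ratio per index increment
#'
#' The magnitude of the odds-ratio change per `delta` units of the index,
#' `exp(|beta1| * delta)`.  The magnitude convention (always >= 1) matches
#' how such ORs are conventionally reported even when the fitted slope is
#' negative; the direction of the association is carried by the slope's
#' sign, not by this number.
#'
#' @param model A `logistic_model`.
#' @param delta Index increment (default 0.001, the WTR reporting step).
#' @return Odds ratio magnitude per `delta`.
#' @examples
#' odds_ratio_per_delta(logistic_model(0.577, -72.8), 0.001) # 1.08
#' @export
odds_ratio_per_delta <- function(model, delta = 0.001) {
  stopifnot(delta > 0)
  exp(abs(model$beta1) * delta)
}

#' Percent difference of a reference from a computed value
#'
#' `|computed - reference| / |computed| * 100`, i.e. the cohort-calculated
#' value is the denominator.
#'
#' @param reference Reference (e.g. theoretical) value.
#' @param computed Cohort-calculated value; must be nonzero.
#' @return Percent difference.
#' @examples
#' percent_difference(6.1e-3, 7.926e-3) # 23
#' @export
percent_difference <- function(reference, computed) {
  if (any(computed == 0)) {
    stop("computed value must be nonzero", call. = FALSE)
  }
  abs(computed - reference) / abs(computed) * 100
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic model for rupture status on ", x$index_name, "\n", sep = "")
  cat(sprintf("  eta = %.4g %+.4g * %s", x$beta0, x$beta1, x$index_name))
  if (!is.na(x$n)) cat(sprintf("   (n = %d)", x$n))
  cat("\n")
  if (!is.na(x$p_value)) {
    cat(sprintf("  slope SE %.3g, Wald p = %.3g\n", x$se_beta1, x$p_value))
  }
  if (x$beta1 != 0) {
    cat(sprintf("  critical value (P = 0.5): %.3g\n", critical_value(x)))
  }
  invisible(x)
}
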