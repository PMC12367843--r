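# Full study-replication pipeline: sphericity screen -> index derivation
# (uncorrected and post-rupture-corrected) -> per-index ROC/LR -> all-site
# and per-site logistic fits -> comparison of the fitted critical WTR
# against the theoretical thin-shell threshold -> report files.

pipeline_indices <- c("WTR", "AR", "BF", "SR",
                      "WTR_prime", "AR_prime", "SR_prime")
pipeline_orientation <- c(WTR = "lower_is_ruptured",
                          AR = "higher_is_ruptured",
                          BF = "higher_is_ruptured",
                          SR = "higher_is_ruptured",
                          WTR_prime = "lower_is_ruptured",
                          AR_prime = "higher_is_ruptured",
                          SR_prime = "higher_is_ruptured")

#' Theoretical critical wall-thickness-to-radius ratio
#'
#' The rupture threshold predicted by the thin-spherical-shell mechanical
#' model of Chaudhry and colleagues (Fung strain-energy wall, rupture
#' stress on the order of 1 MPa): a spherical aneurysm is predicted to
#' rupture when its wall-thickness-to-radius ratio falls to 6.1e-3.
#' Imported here as a named constant; the mechanical derivation itself is
#' outside this package's scope.
#'
#' @return The dimensionless threshold 6.1e-3.
#' @export
theoretical_critical_wtr <- function() 6.1e-3

#' Analysis configuration
#'
#' @param wall_model A [vessel_wall_model()].
#' @param sphericity_threshold Strict upper bound for the sphericity
#'   screen, default 0.2.
#' @param ci_method AUC confidence-interval method, `"delong"` or
#'   `"bootstrap"`.
#' @param boot_n Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param cutoffs Named list of user-supplied cutoffs per index (names
#'   among `WTR`, `AR`, `BF`, `SR`, `WTR_prime`, `AR_prime`, `SR_prime`);
#'   indices without an entry use the Youden-optimal cutoff.
#' @param alpha Significance level for reporting, default 0.05.
#' @param theory_reference Theoretical critical WTR to compare against.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(wall_model = vessel_wall_model(),
                            sphericity_threshold = 0.2,
                            ci_method = c("delong", "bootstrap"),
                            boot_n = 2000,
                            cutoffs = list(),
                            alpha = 0.05,
                            theory_reference = theoretical_critical_wtr()) {
  ci_method <- match.arg(ci_method)
  stopifnot(sphericity_threshold > 0, sphericity_threshold < 1,
            alpha > 0, alpha < 1, theory_reference > 0)
  bad <- setdiff(names(cutoffs), pipeline_indices)
  if (length(bad)) {
    stop("unknown cutoff index name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(wall_model = wall_model,
                 sphericity_threshold = sphericity_threshold,
                 ci_method = ci_method, boot_n = boot_n,
                 cutoffs = cutoffs, alpha = alpha,
                 theory_reference = theory_reference),
            class = "analysis_config")
}

#' Compare a fitted critical value to the theoretical threshold
#'
#' Inverts the model at P = 0.5 and reports the percent difference of the
#' theoretical reference from the cohort-calculated critical value (the
#' calculated value is the denominator).
#'
#' @param model A `logistic_model` with nonzero slope.
#' @param reference Theoretical threshold, default
#'   [theoretical_critical_wtr()].
#' @return A list with `index_name`, `critical_value`, `reference`,
#'   `percent_difference` and a one-line `verdict`.
#' @examples
#' compare_to_theory(logistic_model(0.577, -72.8, "WTR"))
#' @export
compare_to_theory <- function(model, reference = theoretical_critical_wtr()) {
  cv <- critical_value(model)
  pct <- percent_difference(reference, cv)
  list(index_name = model$index_name,
       critical_value = cv,
       reference = reference,
       percent_difference = pct,
       verdict = sprintf(
         "fitted critical %s = %.3g; theoretical threshold %.3g differs by %.1f%%",
         model$index_name, cv, reference, pct))
}

#' Dome wall thickness implied by a critical WTR
#'
#' `t_A = WTR * R_dome`, converted from mm to micrometres.  Evaluating the
#' corrected critical ratio 6.2e-3 at a typical dome radius of 7 mm gives
#' 43.4 um, inside the 30-200 um band reported by histologic studies.
#'
#' @param critical_wtr Dimensionless wall-thickness-to-radius ratio.
#' @param R_dome Dome radius in mm.
#' @return Wall thickness in micrometres.
#' @examples
#' wall_thickness_at(6.2e-3, 7) # 43.4 um
#' @export
wall_thickness_at <- function(critical_wtr, R_dome) {
  check_positive(critical_wtr = critical_wtr, R_dome = R_dome)
  critical_wtr * R_dome * 1000
}

# Internal: fit one logistic model, returning a flagged row on failure.
fit_logistic_row <- function(x, y, index_name, site_label) {
  n <- length(y)
  both <- length(unique(as.logical(y))) == 2
  if (!both || n < 4) {
    return(list(model = NULL,
                row = tibble::tibble(index_name = index_name,
                                     site = site_label, n = n,
                                     beta0 = NA_real_, beta1 = NA_real_,
                                     se_beta1 = NA_real_,
                                     p_value = NA_real_,
                                     critical_value = NA_real_,
                                     or_per_0.001 = NA_real_,
                                     converged = FALSE,
                                     note = "insufficient: single class or n < 4")))
  }
  fit <- tryCatch(fit_logistic(x, y, index_name = index_name),
                  error = function(e) conditionMessage(e))
  if (is.character(fit)) {
    return(list(model = NULL,
                row = tibble::tibble(index_name = index_name,
                                     site = site_label, n = n,
                                     beta0 = NA_real_, beta1 = NA_real_,
                                     se_beta1 = NA_real_,
                                     p_value = NA_real_,
                                     critical_value = NA_real_,
                                     or_per_0.001 = NA_real_,
                                     converged = FALSE, note = fit)))
  }
  cv <- if (fit$beta1 != 0) critical_value(fit) else NA_real_
  list(model = fit,
       row = tibble::tibble(index_name = index_name, site = site_label,
                            n = n, beta0 = fit$beta0, beta1 = fit$beta1,
                            se_beta1 = fit$se_beta1, p_value = fit$p_value,
                            critical_value = cv,
                            or_per_0.001 = odds_ratio_per_delta(fit, 0.001),
                            converged = fit$converged, note = ""))
}

#' Run the full rupture-status analysis on a cohort
#'
#' Screens the cohort for sphericity, derives the seven-index panel (WTR,
#' AR, BF, SR uncorrected; WTR', AR', SR' with the post-rupture height
#' correction applied to ruptured records only - the correction
#' un-inflates post-rupture measurements, so unruptured heights are never
#' touched), runs a ROC/likelihood-ratio analysis per index, fits
#' single-predictor logistic models per index for all sites combined and
#' per site (sites with a single outcome class are flagged rather than
#' failing the run), compares the fitted critical WTR and WTR' against the
#' theoretical threshold, and collects descriptive group comparisons
#' (Welch t-tests on the measured dimensions; chi-squared tests on site,
#' modality and the covariates, covariates compared pairwise-complete).
#'
#' @param cohort An `aneurysm_cohort` (or coercible data frame).
#' @param config An [analysis_config()].
#' @return An object of class `aneurysm_report`: a list with elements
#'   `cohort` (screened records), `excluded`, `indices` (long index table
#'   with a `corrected` flag), `cohort_summary`, `group_comparisons`,
#'   `roc` (named list of [roc_analysis()] objects), `logistic` (fit
#'   table), `logistic_models` (named list of all-site `logistic_model`
#'   objects), `theory` (comparisons against the threshold) and `config`.
#' @export
run_analysis <- function(cohort, config = analysis_config()) {
  cohort <- as_cohort(cohort)
  scr <- screen_spherical(cohort, config$sphericity_threshold)
  kept <- scr$kept
  if (nrow(kept) < 4 || sum(kept$ruptured) < 2 || sum(!kept$ruptured) < 2) {
    stop("analysis requires at least two ruptured and two unruptured ",
         "records after the sphericity screen", call. = FALSE)
  }
  idx_u <- compute_indices(kept, correct_for_rupture = FALSE,
                           model = config$wall_model)
  idx_c <- compute_indices(kept, correct_for_rupture = TRUE,
                           model = config$wall_model)
  panel <- tibble::tibble(WTR = idx_u$WTR, AR = idx_u$AR, BF = idx_u$BF,
                          SR = idx_u$SR, WTR_prime = idx_c$WTR,
                          AR_prime = idx_c$AR, SR_prime = idx_c$SR)
  y <- kept$ruptured

  roc <- lapply(pipeline_indices, function(nm) {
    roc_analysis(panel[[nm]], y, index_name = nm,
                 orientation = pipeline_orientation[[nm]],
                 cutoff = config$cutoffs[[nm]],
                 ci_method = config$ci_method, boot_n = config$boot_n)
  })
  names(roc) <- pipeline_indices

  fits <- list()
  models <- list()
  for (nm in pipeline_indices) {
    all_fit <- fit_logistic_row(panel[[nm]], y, nm, "all")
    fits[[length(fits) + 1L]] <- all_fit$row
    if (!is.null(all_fit$model)) models[[nm]] <- all_fit$model
    for (st in cohort_sites) {
      in_site <- kept$site == st
      fits[[length(fits) + 1L]] <-
        fit_logistic_row(panel[[nm]][in_site], y[in_site], nm, st)$row
    }
  }
  logistic <- do.call(rbind, fits)

  theory <- lapply(intersect(c("WTR", "WTR_prime"), names(models)),
                   function(nm) {
                     compare_to_theory(models[[nm]],
                                       reference = config$theory_reference)
                   })
  names(theory) <- vapply(theory, `[[`, character(1), "index_name")

  neck <- sqrt(kept$d1 * kept$d2)
  gc_rows <- list()
  add_welch <- function(vals, label) {
    a <- vals[y]
    b <- vals[!y]
    row <- tryCatch(welch_t_test(a, b, variable = label),
                    error = function(e) NULL)
    if (!is.null(row)) gc_rows[[length(gc_rows) + 1L]] <<- row
  }
  add_welch(kept$h, "h")
  add_welch(kept$w, "w")
  add_welch(kept$r, "r")
  add_welch(neck, "neck_geometric_mean")
  add_chisq <- function(tab, label) {
    row <- tryCatch(chi_squared_test(tab, variable = label),
                    error = function(e) NULL)
    if (!is.null(row)) gc_rows[[length(gc_rows) + 1L]] <<- row
  }
  add_chisq(table(y, kept$site), "site")
  add_chisq(table(y, kept$modality), "modality")
  for (cov in c("smoking", "hypertension")) {
    ok <- !is.na(kept[[cov]]) # pairwise-complete
    if (sum(ok) > 0) add_chisq(table(y[ok], kept[[cov]][ok]), cov)
  }
  group_comparisons <- if (length(gc_rows)) {
    do.call(rbind, gc_rows)
  } else {
    tibble::tibble(variable = character(), test = character(),
                   statistic = double(), df = double(), p_value = double())
  }

  counts <- as.data.frame(table(site = kept$site, ruptured = kept$ruptured))
  cohort_summary <- tibble::as_tibble(counts)
  cohort_summary$ruptured <- as.logical(cohort_summary$ruptured)
  cohort_summary$site <- as.character(cohort_summary$site)
  names(cohort_summary)[names(cohort_summary) == "Freq"] <- "n"

  indices_long <- rbind(
    cbind(tibble::tibble(id = kept$id, site = kept$site,
                         ruptured = kept$ruptured), idx_u),
    cbind(tibble::tibble(id = kept$id, site = kept$site,
                         ruptured = kept$ruptured), idx_c)
  )

  structure(list(cohort = kept, excluded = scr$excluded,
                 indices = tibble::as_tibble(indices_long),
                 cohort_summary = cohort_summary,
                 group_comparisons = group_comparisons,
                 roc = roc, logistic = logistic,
                 logistic_models = models, theory = theory,
                 config = config),
            class = "aneurysm_report")
}

#' @export
print.aneurysm_report <- function(x, ...) {
  n <- nrow(x$cohort)
  cat("Aneurysm rupture-status analysis\n")
  cat(sprintf("  %d records analysed (%d ruptured, %d unruptured); %d excluded by sphericity screen\n",
              n, sum(x$cohort$ruptured), sum(!x$cohort$ruptured),
              nrow(x$excluded)))
  cat("  AUCs (95% CI):\n")
  for (nm in names(x$roc)) {
    r <- x$roc[[nm]]
    cat(sprintf("    %-9s %.3f (%.3f-%.3f)  cutoff %.4g  sens %.1f%%  spec %.1f%%  LR+ %.3g\n",
                nm, r$auc, r$auc_ci[["low"]], r$auc_ci[["high"]],
                r$chosen_cutoff, 100 * r$sens, 100 * r$spec, r$positive_lr))
  }
  for (th in x$theory) cat("  ", th$verdict, "\n", sep = "")
  invisible(x)
}

# Internal: full-precision CSV writer (doubles via as.character, ~15 sig
# digits, so round trips hold to >= 12 significant digits).
write_full_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE)
}

#' Write analysis outputs to a directory
#'
#' For a full report: `indices.csv` (long per-record index table with a
#' `corrected` flag), one `roc_points_<index>.csv` per index,
#' `logistic_fits.csv`, `group_comparisons.csv` and a human-readable
#' `summary.json` (numbers to 3 significant figures; the CSVs keep full
#' precision).  For a bare cohort table the per-record indices and a count
#' summary are written; an empty cohort yields only a zero-count summary.
#'
#' @param x An `aneurysm_report` from [run_analysis()], or a cohort table.
#' @param path Output directory (created if needed).
#' @return A tibble manifest of the files written (`file`, `rows`).
#' @export
write_results <- function(x, path) {
  if (!dir.exists(path)) {
    ok <- tryCatch(dir.create(path, recursive = TRUE),
                   warning = function(w) FALSE)
    if (!isTRUE(ok)) stop("cannot create output directory: ", path,
                          call. = FALSE)
  }
  if (file.access(path, 2) != 0) {
    stop("output directory not writable: ", path, call. = FALSE)
  }
  manifest <- list()
  emit <- function(df, name) {
    write_full_csv(df, file.path(path, name))
    manifest[[length(manifest) + 1L]] <<-
      tibble::tibble(file = name, rows = nrow(df))
  }
  s3 <- function(v) if (is.numeric(v)) signif(v, 3) else v

  if (inherits(x, "aneurysm_report")) {
    ind <- x$indices
    out_ind <- tibble::tibble(id = ind$id, site = ind$site,
                              ruptured = as.integer(ind$ruptured),
                              t_V_mm = ind$t_V, t_A_mm = ind$t_A,
                              R_dome_mm = ind$R_dome, WTR = ind$WTR,
                              AR = ind$AR, BF = ind$BF, SR = ind$SR,
                              sphericity = ind$sphericity,
                              corrected = as.integer(ind$corrected))
    emit(out_ind, "indices.csv")
    for (nm in names(x$roc)) {
      pts <- x$roc[[nm]]$points
      pts$one_minus_spec <- 1 - pts$spec
      emit(pts, paste0("roc_points_", nm, ".csv"))
    }
    emit(x$logistic, "logistic_fits.csv")
    emit(x$group_comparisons, "group_comparisons.csv")
    summary <- list(
      n_analysed = nrow(x$cohort),
      n_ruptured = sum(x$cohort$ruptured),
      n_unruptured = sum(!x$cohort$ruptured),
      n_excluded_sphericity = nrow(x$excluded),
      counts_by_site = lapply(split(x$cohort_summary$n,
                                    x$cohort_summary$site), sum),
      roc = lapply(x$roc, function(r) {
        list(auc = s3(r$auc),
             auc_ci = s3(unname(r$auc_ci)),
             cutoff = s3(r$chosen_cutoff),
             sensitivity = s3(r$sens), specificity = s3(r$spec),
             positive_lr = s3(r$positive_lr),
             lr_ci = s3(unname(c(r$lr_ci))))
      }),
      critical_values = lapply(x$logistic_models, function(m) {
        s3(critical_value(m))
      }),
      theory = lapply(x$theory, function(th) {
        list(reference = s3(th$reference),
             critical_value = s3(th$critical_value),
             percent_difference = s3(th$percent_difference))
      })
    )
    jsonlite::write_json(summary, file.path(path, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest[[length(manifest) + 1L]] <-
      tibble::tibble(file = "summary.json", rows = NA_integer_)
  } else {
    cohort <- as_cohort(x)
    if (nrow(cohort) > 0) {
      idx <- compute_indices(cohort)
      out_ind <- tibble::tibble(id = cohort$id, site = cohort$site,
                                ruptured = as.integer(cohort$ruptured),
                                t_V_mm = idx$t_V, t_A_mm = idx$t_A,
                                R_dome_mm = idx$R_dome, WTR = idx$WTR,
                                AR = idx$AR, BF = idx$BF, SR = idx$SR,
                                sphericity = idx$sphericity,
                                corrected = as.integer(idx$corrected))
      emit(out_ind, "indices.csv")
    }
    summary <- list(n_records = nrow(cohort),
                    n_ruptured = sum(cohort$ruptured),
                    n_unruptured = sum(!cohort$ruptured))
    jsonlite::write_json(summary, file.path(path, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest[[length(manifest) + 1L]] <-
      tibble::tibble(file = "summary.json", rows = NA_integer_)
  }
  do.call(rbind, manifest)
}
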