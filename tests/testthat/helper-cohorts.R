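# Shared fixtures and independent oracles.

# Brute-force AUC oracle: fraction of (case, control) pairs won, ties half.
brute_force_auc <- function(scores, labels) {
  cs <- scores[as.logical(labels)]
  ct <- scores[!as.logical(labels)]
  mean(outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b)))
}

# A small, fully valid cohort with hand-picked dimensions.
toy_cohort <- function() {
  as_cohort(tibble::tibble(
    id = c("a1", "a2", "a3", "a4", "a5", "a6"),
    h = c(5.0, 6.0, 7.0, 4.0, 8.0, 5.5),
    w = c(4.5, 6.3, 6.5, 4.2, 7.6, 5.0),
    d1 = c(3.0, 3.5, 4.0, 2.5, 4.5, 3.0),
    d2 = c(2.5, 3.0, 3.5, 2.0, 4.0, 2.8),
    r = c(1.5, 1.2, 1.8, 1.0, 2.0, 1.4),
    site = c("BT", "Acom", "Pcom", "BT", "Acom", "Pcom"),
    ruptured = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  ))
}

# Random record generator for property loops (valid by construction).
random_records <- function(n) {
  h <- runif(n, 3, 10)
  tibble::tibble(
    h = h,
    w = h * runif(n, 0.85, 1.15),
    d1 = runif(n, 2, 5),
    d2 = runif(n, 2, 5),
    r = runif(n, 0.8, 2.5),
    ruptured = runif(n) < 0.4
  )
}

# Write a cohort CSV from raw text lines (header included).
write_csv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

cohort_csv_header <-
  "id,h_mm,w_mm,d1_mm,d2_mm,r_mm,site,ruptured,modality,smoking,hypertension"
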