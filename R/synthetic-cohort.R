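# Synthetic measurement cohorts with the statistical structure the
# analysis assumes: mm-scale lognormal morphometry, a width tightly coupled
# to height (so the sphericity screen retains essentially all records), an
# elliptical neck with bounded eccentricity, and rupture labels linked to
# WTR through a configurable logistic model, optionally followed by the
# 14.9% post-rupture height inflation.

#' Configuration of the synthetic cohort generator
#'
#' Defaults mirror the validation study's design where it is printed:
#' group sizes 52 unruptured / 28 ruptured, site mix proportional to the
#' reported site counts (51 BT / 15 Acom / 14 Pcom), smoking and
#' hypertension prevalences 80% and 78.75%, and the published all-site
#' logistic link on WTR (beta0 = 0.577, beta1 = -72.8).  The morphometry
#' medians (h 6 mm, neck 4 mm, r 1.3 mm, lognormal) are plausible-scale
#' choices, fully configurable, with the parent-vessel radius kept inside
#' the wall model's validity range.
#'
#' @param n_unruptured,n_ruptured Group sizes for the default
#'   fixed-group-size (case-control style) generation.
#' @param site_mix Named probabilities over BT/Acom/Pcom, summing to 1.
#' @param h_median,h_gsd Lognormal median (mm) and geometric SD (>= 1) of
#'   aneurysm height.
#' @param neck_median,neck_gsd Lognormal law of the neck geometric-mean
#'   diameter (mm).
#' @param r_median,r_gsd Lognormal law of the parent-vessel radius (mm);
#'   draws at or above 3.9 mm are resampled so every record passes the
#'   vessel-wall model's validity guard.
#' @param width_coupling Half-width of the uniform relative deviation of
#'   width from height: `w = h * (1 + u)`, `u ~ U(-c, c)`.  At the default
#'   0.18 the sphericity index never exceeds 0.099, so the screen keeps
#'   every record.
#' @param eccentricity_max Maximum neck-ellipse axis ratio `d1/d2`; the
#'   eccentricity is uniform on `[1, eccentricity_max]` and the axes
#'   preserve the drawn geometric mean.
#' @param link Numeric `c(beta0, beta1)` of the rupture-probability
#'   logistic on WTR, `P = plogis(beta0 + beta1 * WTR)`.
#' @param apply_rupture_inflation Multiply the height of ruptured records
#'   by 1.149 after label assignment, emulating post-rupture measurement?
#' @param smoking_prev,hypertension_prev Bernoulli prevalences of the
#'   covariates, drawn independently of morphometry.
#' @param modality_mix Named probabilities over CTA/MRA/DSA.
#' @param seed Integer seed; all draws flow from one generator stream in
#'   documented order, so cohorts are bit-reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_unruptured = 52, n_ruptured = 28,
                          site_mix = c(BT = 0.6375, Acom = 0.1875,
                                       Pcom = 0.175),
                          h_median = 6, h_gsd = 1.4,
                          neck_median = 4, neck_gsd = 1.3,
                          r_median = 1.3, r_gsd = 1.25,
                          width_coupling = 0.18,
                          eccentricity_max = 1.5,
                          link = c(beta0 = 0.577, beta1 = -72.8),
                          apply_rupture_inflation = TRUE,
                          smoking_prev = 0.80, hypertension_prev = 0.7875,
                          modality_mix = c(CTA = 0.5, MRA = 0.25,
                                           DSA = 0.25),
                          seed = 1L) {
  stopifnot(n_unruptured >= 0, n_ruptured >= 0,
            all(site_mix >= 0), abs(sum(site_mix) - 1) < 1e-8,
            all(names(site_mix) %in% cohort_sites),
            h_median > 0, h_gsd >= 1, neck_median > 0, neck_gsd >= 1,
            r_median > 0, r_gsd >= 1,
            width_coupling >= 0, width_coupling < 1,
            eccentricity_max >= 1,
            length(link) == 2, all(is.finite(link)),
            smoking_prev >= 0, smoking_prev <= 1,
            hypertension_prev >= 0, hypertension_prev <= 1,
            all(modality_mix >= 0), abs(sum(modality_mix) - 1) < 1e-8,
            length(seed) == 1, is.finite(seed))
  structure(list(n_unruptured = as.integer(n_unruptured),
                 n_ruptured = as.integer(n_ruptured),
                 site_mix = site_mix,
                 h_median = h_median, h_gsd = h_gsd,
                 neck_median = neck_median, neck_gsd = neck_gsd,
                 r_median = r_median, r_gsd = r_gsd,
                 width_coupling = width_coupling,
                 eccentricity_max = eccentricity_max,
                 link = c(beta0 = unname(link[1]), beta1 = unname(link[2])),
                 apply_rupture_inflation = isTRUE(apply_rupture_inflation),
                 smoking_prev = smoking_prev,
                 hypertension_prev = hypertension_prev,
                 modality_mix = modality_mix,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Internal: one batch of labelled morphometry draws.
draw_labelled_records <- function(n, config, model) {
  h <- stats::rlnorm(n, log(config$h_median), log(config$h_gsd))
  u <- if (config$width_coupling > 0) {
    stats::runif(n, -config$width_coupling, config$width_coupling)
  } else rep(0, n)
  w <- h * (1 + u)
  g <- stats::rlnorm(n, log(config$neck_median), log(config$neck_gsd))
  ecc <- if (config$eccentricity_max > 1) {
    stats::runif(n, 1, config$eccentricity_max)
  } else rep(1, n)
  d1 <- g * sqrt(ecc)
  d2 <- g / sqrt(ecc)
  r <- stats::rlnorm(n, log(config$r_median), log(config$r_gsd))
  bad <- r >= 3.9 # stay inside the t_V validity range
  while (any(bad)) {
    r[bad] <- stats::rlnorm(sum(bad), log(config$r_median),
                            log(config$r_gsd))
    bad <- r >= 3.9
  }
  rec <- tibble::tibble(h = h, w = w, d1 = d1, d2 = d2, r = r)
  wtr <- compute_indices(rec, model = model)$WTR
  p <- stats::plogis(config$link[["beta0"]] + config$link[["beta1"]] * wtr)
  rec$ruptured <- stats::runif(n) < p
  rec
}

#' Generate a synthetic aneurysm cohort
#'
#' Draws morphometry from the configured lognormal laws, computes each
#' record's (uncorrected) WTR, and assigns rupture labels through the
#' configured logistic link.  By default the configured group sizes are
#' filled by rejection sampling (case-control style, mirroring a
#' pre-stratified study design): records are drawn, labelled, and kept
#' until each group is full.  Supplying `n_total` instead switches to
#' prospective sampling - exactly `n_total` records with labels at their
#' natural frequency under the link - which is the mode used for
#' parameter-recovery experiments, since fixed group fractions shift the
#' recoverable intercept.
#'
#' If `apply_rupture_inflation` is set, heights of ruptured records are
#' multiplied by 1.149 after label assignment, so the recorded
#' measurements emulate post-rupture imaging; [compute_indices()] with
#' `correct_for_rupture = TRUE` then recovers the pre-inflation heights
#' exactly.
#'
#' Generation is deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param n_total If supplied, prospective sample size (overrides the
#'   configured group sizes).
#' @return An `aneurysm_cohort` tibble passing strict validation.
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' table(coh$ruptured)
#' @export
generate_cohort <- function(config = cohort_config(), n_total = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  model <- vessel_wall_model()
  if (!is.null(n_total)) {
    stopifnot(n_total >= 0)
    rec <- draw_labelled_records(as.integer(n_total), config, model)
  } else {
    need_r <- config$n_ruptured
    need_u <- config$n_unruptured
    if (need_r == 0 && need_u == 0) {
      return(as_cohort(tibble::tibble(id = character(), h = double(),
                                      w = double(), d1 = double(),
                                      d2 = double(), r = double(),
                                      site = character(),
                                      ruptured = logical()),
                       provenance = "synthetic cohort (empty)"))
    }
    got_r <- list()
    got_u <- list()
    rounds <- 0L
    while ((need_r > 0 || need_u > 0) && rounds < 1000L) {
      rounds <- rounds + 1L
      m <- max(200L, 4L * (need_r + need_u))
      batch <- draw_labelled_records(m, config, model)
      if (need_r > 0) {
        take <- utils::head(which(batch$ruptured), need_r)
        got_r[[rounds]] <- batch[take, , drop = FALSE]
        need_r <- need_r - length(take)
      }
      if (need_u > 0) {
        take <- utils::head(which(!batch$ruptured), need_u)
        got_u[[rounds]] <- batch[take, , drop = FALSE]
        need_u <- need_u - length(take)
      }
    }
    if (need_r > 0 || need_u > 0) {
      stop("unreachable group sizes: the link produced too few ",
           if (need_r > 0) "ruptured" else "unruptured",
           " records after ", rounds, " rejection rounds", call. = FALSE)
    }
    rec <- rbind(do.call(rbind, got_u), do.call(rbind, got_r))
  }
  n <- nrow(rec)
  if (config$apply_rupture_inflation && n > 0) {
    rec$h[rec$ruptured] <- rec$h[rec$ruptured] * 1.149
  }
  rec$id <- sprintf("ia%05d", seq_len(n))
  rec$site <- if (n > 0) {
    sample(names(config$site_mix), n, replace = TRUE,
           prob = config$site_mix)
  } else character()
  rec$modality <- if (n > 0) {
    sample(names(config$modality_mix), n, replace = TRUE,
           prob = config$modality_mix)
  } else character()
  rec$smoking <- stats::runif(n) < config$smoking_prev
  rec$hypertension <- stats::runif(n) < config$hypertension_prev
  as_cohort(rec, provenance = sprintf("synthetic cohort (seed %d)",
                                      config$seed))
}

#' Build a score table with exact confusion counts
#'
#' Places labelled scores deterministically on either side of a cutoff so
#' that [sens_spec_at_cutoff()] at that cutoff returns exactly
#' `tp/(tp+fn)` and `tn/(tn+fp)`.  All scores are distinct, so AUCs on the
#' table are tie-free.  Intended as a fixture builder for published
#' sensitivity/specificity rows.
#'
#' @param tp,fn,tn,fp Confusion counts (non-negative).
#' @param cutoff Cutoff value to build around.
#' @param orientation Call rule; for `"lower_is_ruptured"` (default,
#'   matching the WTR family) positive calls sit below the cutoff.
#' @param index_name Label for the score column.
#' @return A tibble with columns `id`, `score`, `ruptured`; the cutoff and
#'   orientation are attached as attributes.
#' @export
generate_confusion_cohort <- function(tp, fn, tn, fp, cutoff,
                                      orientation = "lower_is_ruptured",
                                      index_name = "score") {
  orientation <- match.arg(orientation, roc_orientations)
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  np <- tp + fp # positive-side calls
  nn <- fn + tn
  eps <- 0.01 * max(abs(cutoff), 1)
  if (orientation == "lower_is_ruptured") {
    pos_side <- cutoff - eps * seq_len(np)
    neg_side <- cutoff + eps * seq_len(nn)
  } else {
    pos_side <- cutoff + eps * seq_len(np)
    neg_side <- cutoff - eps * seq_len(nn)
  }
  score <- c(pos_side, neg_side)
  ruptured <- c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn), rep(FALSE, tn))
  out <- tibble::tibble(id = sprintf("s%04d", seq_along(score)),
                        score = score, ruptured = ruptured)
  attr(out, "cutoff") <- cutoff
  attr(out, "orientation") <- orientation
  attr(out, "index_name") <- index_name
  out
}
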