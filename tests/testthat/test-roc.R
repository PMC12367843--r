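test_that("midrank AUC matches the exhaustive pairwise oracle", {
  # frozen small cases
  expect_equal(auc_midrank(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auc_midrank(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.25)
  expect_equal(auc_midrank(c(1, 1), c(TRUE, FALSE)), 0.5)
  expect_error(auc_midrank(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # random instances with heavy ties, n <= 30, against brute force
  set.seed(19)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    scores <- sample(1:6, n, replace = TRUE) # many ties
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5) # both classes guaranteed
    expect_equal(auc_midrank(scores, labels),
                 brute_force_auc(scores, labels))
  }
})

test_that("midrank AUC agrees with an independent ROC implementation", {
  set.seed(23)
  scores <- rnorm(80)
  labels <- runif(80) < plogis(scores)
  labels[1:2] <- c(TRUE, FALSE)
  ours <- auc_midrank(scores, labels)
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                           levels = c(FALSE, TRUE),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs)
})

test_that("orientation is coherent: lower-is-ruptured equals negated higher", {
  set.seed(5)
  x <- c(rnorm(20), rnorm(5)[c(1, 1, 2, 3, 4)]) # include ties
  y <- runif(25) < 0.4
  y[1:2] <- c(TRUE, FALSE)
  lower <- roc_points(x, y, "lower_is_ruptured")
  higher <- roc_points(-x, y, "higher_is_ruptured")
  # same curve point-for-point after mapping cutoffs c -> -c
  reord <- higher[match(-lower$cutoff, higher$cutoff), ]
  expect_equal(reord$sens, lower$sens)
  expect_equal(reord$spec, lower$spec)
  # oriented AUCs are complementary
  expect_equal(auc_midrank(-x, y), 1 - auc_midrank(x, y))
})

test_that("AUC confidence intervals bracket the estimate and flip with labels", {
  set.seed(41)
  scores <- rnorm(200)
  labels <- runif(200) < plogis(1.5 * scores)
  labels[1:2] <- c(TRUE, FALSE)
  auc <- auc_midrank(scores, labels)
  ci <- auc_ci(scores, labels)
  expect_lt(ci[["low"]], auc)
  expect_gt(ci[["high"]], auc)
  # flipping the labels maps (a, b) to (1-b, 1-a)
  flipped <- auc_ci(scores, !labels)
  expect_equal(unname(flipped), unname(1 - rev(ci)))
  # DeLong and stratified bootstrap agree closely at n = 200
  set.seed(42)
  boot <- auc_ci(scores, labels, method = "bootstrap", boot_n = 2000)
  expect_lt(max(abs(boot - ci)), 0.03)
  # too-small classes refuse an interval
  expect_error(auc_ci(c(1, 2, 3), c(TRUE, FALSE, FALSE)), "two observations")
})

test_that("sensitivity/specificity at a cutoff follow the inclusive call rule", {
  # all cases below, all controls above, lower_is_ruptured: perfect
  expect_equal(sens_spec_at_cutoff(c(1, 2, 5, 6), c(TRUE, TRUE, FALSE, FALSE),
                                   3, "lower_is_ruptured"),
               c(sensitivity = 1, specificity = 1))
  # no positive calls: sens 0, spec 1
  expect_equal(sens_spec_at_cutoff(c(5, 6, 7, 8), c(TRUE, TRUE, FALSE, FALSE),
                                   1, "lower_is_ruptured"),
               c(sensitivity = 0, specificity = 1))
  # cutoff is inclusive on the positive side
  expect_equal(sens_spec_at_cutoff(c(3, 4), c(TRUE, FALSE), 3,
                                   "lower_is_ruptured")[["sensitivity"]], 1)
  # printed worked example: 23/28 and 32/52
  cc <- generate_confusion_cohort(23, 5, 32, 20, cutoff = 1.49e-2)
  ss <- sens_spec_at_cutoff(cc$score, cc$ruptured, 1.49e-2,
                            "lower_is_ruptured")
  expect_equal(ss[["sensitivity"]], 23 / 28)
  expect_equal(ss[["specificity"]], 32 / 52)
})

test_that("Youden cutoff maximises J with the documented tie-breaks", {
  # enumerated optimum in the separating gap, reported at the midpoint
  expect_equal(youden_cutoff(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                             "lower_is_ruptured"), 2.5)
  expect_equal(youden_cutoff(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                             "higher_is_ruptured"), 2.5)
  # single distinct value: J = 0, cutoff at the value itself
  expect_equal(youden_cutoff(rep(2, 4), c(TRUE, FALSE, TRUE, FALSE),
                             "lower_is_ruptured"), 2)
  # exhaustive check on random instances
  set.seed(13)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    cut <- youden_cutoff(x, y, "lower_is_ruptured")
    jmax <- max(vapply(sort(unique(x)), function(cc) {
      ss <- sens_spec_at_cutoff(x, y, cc, "lower_is_ruptured")
      ss[[1]] + ss[[2]] - 1
    }, numeric(1)))
    ss <- sens_spec_at_cutoff(x, y, cut, "lower_is_ruptured")
    expect_equal(ss[[1]] + ss[[2]] - 1, jmax)
  }
})

test_that("positive LR and its log-method interval reproduce printed values", {
  expect_equal(positive_lr(0.5, 0.5), 1.0)
  expect_equal(round(positive_lr(23 / 28, 32 / 52), 2), 2.14)
  expect_equal(round(positive_lr(26 / 28, 24 / 52), 2), 1.72)
  expect_warning(inf_lr <- positive_lr(0.9, 1), "infinite")
  expect_identical(inf_lr, Inf)

  ci <- lr_ci(23, 5, 32, 20)
  expect_lt(ci[["low"]], 2.14)
  expect_gt(ci[["high"]], 2.14)
  expect_equal(as.numeric(ci), c(1.45, 3.14), tolerance = 0.05 / 1.45)
  expect_false(attr(ci, "continuity_corrected"))
  # an uninformative test has an interval containing 1
  flat <- lr_ci(50, 50, 50, 50)
  expect_lt(flat[["low"]], 1)
  expect_gt(flat[["high"]], 1)
  # doubling all counts narrows the interval
  doubled <- lr_ci(46, 10, 64, 40)
  expect_lt(doubled[["high"]] - doubled[["low"]],
            ci[["high"]] - ci[["low"]])
  # zero cells trigger the flagged continuity correction
  zc <- lr_ci(10, 0, 10, 0)
  expect_true(attr(zc, "continuity_corrected"))
  expect_true(all(is.finite(zc)))
})

test_that("LR degenerates to the uninformative boundary at extreme cutoffs", {
  set.seed(3)
  x <- rnorm(40)
  y <- c(TRUE, FALSE, runif(38) < 0.5)
  lo <- sens_spec_at_cutoff(x, y, min(x) - 1, "lower_is_ruptured")
  hi <- sens_spec_at_cutoff(x, y, max(x) + 1, "lower_is_ruptured")
  expect_equal(unname(lo), c(0, 1)) # nobody called positive
  expect_equal(unname(hi), c(1, 0)) # everybody called positive
  expect_equal(positive_lr(hi[[1]], hi[[2]]), 1) # sens and 1-spec both 1
})

test_that("roc_analysis bundles a self-consistent summary", {
  set.seed(8)
  rec <- random_records(60)
  wtr <- compute_indices(rec)$WTR
  y <- rec$ruptured
  ra <- roc_analysis(wtr, y, "WTR", "lower_is_ruptured")
  expect_s3_class(ra, "roc_analysis")
  expect_equal(ra$auc, auc_midrank(-wtr, y))
  expect_true(ra$auc_ci[["low"]] <= ra$auc && ra$auc <= ra$auc_ci[["high"]])
  ss <- sens_spec_at_cutoff(wtr, y, ra$chosen_cutoff, "lower_is_ruptured")
  expect_equal(ra$sens, ss[["sensitivity"]])
  expect_equal(ra$spec, ss[["specificity"]])
  expect_equal(ra$positive_lr, positive_lr(ra$sens, ra$spec))
  expect_equal(sum(ra$counts), length(wtr))
  # a user-supplied cutoff is honoured
  ra2 <- roc_analysis(wtr, y, "WTR", "lower_is_ruptured", cutoff = 0.01)
  expect_equal(ra2$chosen_cutoff, 0.01)
})
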