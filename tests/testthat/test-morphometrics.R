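test_that("sphericity index matches hand arithmetic and screens strictly", {
  expect_equal(sphericity_index(10, 10), 0)
  expect_equal(sphericity_index(10, 7), 3 / 17)
  expect_equal(sphericity_index(10, 6), 0.25)
  expect_error(sphericity_index(-1, 5), "domain")

  coh <- tibble::tibble(id = c("x1", "x2", "x3"),
                        h = c(10, 10, 10), w = c(10, 7, 6))
  scr <- screen_spherical(coh)
  expect_equal(scr$kept$id, c("x1", "x2"))
  expect_equal(scr$excluded$id, "x3")
  # boundary: index exactly at the threshold is excluded (strict <)
  at_boundary <- tibble::tibble(h = 3, w = 2) # |1|/5 = 0.2
  expect_equal(nrow(screen_spherical(at_boundary)$kept), 0)
  # empty cohort passes through
  empty <- screen_spherical(coh[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$excluded), 0)
})

test_that("vessel wall thickness follows the linear law inside its validity", {
  expect_equal(vessel_wall_thickness(1.5), 0.22245)
  expect_equal(vessel_wall_thickness(1.0), 0.178)
  # beyond the zero crossing of the thickness-to-diameter ratio (~3.996 mm)
  expect_error(vessel_wall_thickness(4.5), "validity")
  expect_error(vessel_wall_thickness(0.1187 / 0.0297), "validity")
  # custom coefficients move the validity bound
  expect_gt(vessel_wall_thickness(4.5, vessel_wall_model(0, 0.1)), 0)
})

test_that("dome thickness, dome radius and height correction match hand values", {
  expect_equal(aneurysm_wall_thickness(10, 10, 4, 4, 0.22245), 0.008898)
  # neck area equal to projected dome area: t_A = t_V
  expect_equal(aneurysm_wall_thickness(2, 2, 4, 4, 0.2), 0.2)
  expect_equal(dome_radius(10, 10), 5)
  expect_equal(dome_radius(4, 9), 3)
  expect_equal(dome_radius(3 * 4, 3 * 9), 3 * 3) # homogeneity of degree 1
  expect_equal(apply_height_correction(1.149), 1.0)
  expect_equal(apply_height_correction(11.49), 10.0)
  expect_error(dome_radius(0, 1), "domain")
  expect_error(apply_height_correction(0), "domain")
})

test_that("the index panel reproduces the hand-chained example", {
  rec <- tibble::tibble(h = 10, w = 10, d1 = 4, d2 = 4, r = 1.5)
  ix <- compute_indices(rec)
  expect_equal(ix$WTR, 1.7796e-3)
  expect_equal(ix$AR, 2.5)
  expect_equal(ix$BF, 2.5)
  expect_equal(ix$SR, 10 / 3)
  expect_equal(ix$t_A, ix$WTR * ix$R_dome) # definitional identity
  expect_false(ix$corrected)
  # height equal to the neck geometric mean gives AR = 1
  ar1 <- compute_indices(tibble::tibble(h = 6, w = 6, d1 = 4, d2 = 9,
                                        r = 1.2))
  expect_equal(ar1$AR, 1.0)
})

test_that("indices obey scale invariance, symmetry and the closed-form oracle", {
  set.seed(31)
  for (i in 1:25) {
    rec <- random_records(1)
    ix <- compute_indices(rec)
    # closed form WTR = d1*d2*t_V / (2*(h*w)^1.5)
    t_V <- vessel_wall_thickness(rec$r)
    closed <- rec$d1 * rec$d2 * t_V / (2 * (rec$h * rec$w)^1.5)
    expect_equal(ix$WTR, closed, tolerance = 1e-12)
    # d1 <-> d2 swap leaves every index unchanged
    swapped <- rec
    swapped[, c("d1", "d2")] <- rec[, c("d2", "d1")]
    expect_equal(compute_indices(swapped), ix)
    # scaling all lengths by k: AR, BF, SR, sphericity invariant
    k <- runif(1, 0.5, 1.5) # keep r inside model validity
    scaled <- rec
    scaled[, c("h", "w", "d1", "d2", "r")] <-
      rec[, c("h", "w", "d1", "d2", "r")] * k
    ixs <- compute_indices(scaled)
    expect_equal(ixs$AR, ix$AR)
    expect_equal(ixs$BF, ix$BF)
    expect_equal(ixs$SR, ix$SR)
    expect_equal(ixs$sphericity, ix$sphericity)
    # ... but WTR is not scale-invariant (t_V is nonlinear in r)
    if (abs(k - 1) > 1e-3) expect_false(isTRUE(all.equal(ixs$WTR, ix$WTR)))
  }
})

test_that("WTR is monotone in each dimension in the expected direction", {
  base <- tibble::tibble(h = 6, w = 6, d1 = 4, d2 = 3.5, r = 1.3)
  wtr <- function(rec) compute_indices(rec)$WTR
  bump <- function(col, delta) {
    rec <- base
    rec[[col]] <- rec[[col]] + delta
    rec
  }
  for (d in c(0.2, 1, 2)) {
    expect_lt(wtr(bump("h", d)), wtr(base)) # decreasing in h
    expect_lt(wtr(bump("w", d)), wtr(base)) # decreasing in w
    expect_gt(wtr(bump("d1", d)), wtr(base)) # increasing in d1
    expect_gt(wtr(bump("d2", d)), wtr(base)) # increasing in d2
  }
})

test_that("the post-rupture correction moves indices in the proven direction", {
  set.seed(77)
  rec <- random_records(30)
  rec$ruptured <- TRUE # correction applies to ruptured records
  unc <- compute_indices(rec, correct_for_rupture = FALSE)
  cor <- compute_indices(rec, correct_for_rupture = TRUE)
  expect_true(all(cor$WTR > unc$WTR))
  expect_true(all(cor$AR < unc$AR))
  expect_true(all(cor$SR <= unc$SR))
  expect_equal(cor$BF, unc$BF) # bottleneck factor is never corrected
  # SR' equals SR exactly when the width dominates both heights
  wide <- tibble::tibble(h = 5, w = 6, d1 = 3, d2 = 3, r = 1.2,
                         ruptured = TRUE)
  expect_equal(compute_indices(wide, TRUE)$SR,
               compute_indices(wide, FALSE)$SR)
  # unruptured records are untouched by the corrected variant
  mixed <- rec
  mixed$ruptured <- rep(c(TRUE, FALSE), 15)
  mix_cor <- compute_indices(mixed, correct_for_rupture = TRUE)
  mix_unc <- compute_indices(mixed, correct_for_rupture = FALSE)
  expect_equal(mix_cor$WTR[!mixed$ruptured], mix_unc$WTR[!mixed$ruptured])
})
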