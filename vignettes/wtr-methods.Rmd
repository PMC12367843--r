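---
title: "Geometric wall-thickness morphometrics and rupture-status analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric wall-thickness morphometrics and rupture-status analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneurysmorph)
```

## The model

Intracranial aneurysms (IAs) rupture when wall stress exceeds wall
strength, and wall thickness is central to both — yet thickness cannot be
measured on routine angiography. A thin-spherical-shell mechanical model of
near-spherical IAs (Chaudhry and colleagues; Fung strain-energy wall,
rupture stress of order 1 MPa) predicts rupture when the
**wall-thickness-to-radius ratio** falls to a critical value of
$6.1\times10^{-3}$. This package implements a geometric route from five 2D
measurements per aneurysm — height $h$, width $w$, two perpendicular neck
diameters $d_1, d_2$, and parent-vessel radius $r$, all in mm — to that
ratio, and the statistical machinery to ask whether it separates ruptured
from unruptured lesions.

The chain is:

1. **Parent-vessel wall thickness.** Intra-operative measurements of
   cerebral vessels support a linear relation between the
   thickness-to-diameter ratio and the radius, so
   $t_V = (\beta r + \alpha)\,2r$ with defaults $\beta = -0.0297$ per mm
   and $\alpha = 0.1187$. The linear ratio crosses zero near
   $r \approx 3.996$ mm; beyond that the model is meaningless, so
   `vessel_wall_thickness()` raises an error rather than clamping — a
   clamped $t_V = 0$ would silently zero every downstream index. The
   coefficients are arguments of `vessel_wall_model()`, so a refitted
   vessel-wall correlation can be substituted without touching anything
   else.

2. **Dome wall thickness by material conservation.** The dome is assumed
   to be parent-vessel wall stretched over a sphere: the wall volume of
   the elliptical neck disc (axes $d_1, d_2$) is spread over the dome
   surface, giving
   $t_A = \frac{d_1 d_2}{4hw}\,t_V$.

3. **Normalisation.** With dome radius $R_{dome} = \sqrt{hw}/2$ (half the
   geometric-mean diameter),
   $\mathrm{WTR} = t_A / R_{dome}$.

The comparator indices are the classical morphometrics: aspect ratio
$AR = h/\sqrt{d_1 d_2}$, bottleneck factor $BF = w/\sqrt{d_1 d_2}$ and
size ratio $SR = \max(h, w)/2r$. All of $AR$, $BF$, $SR$ and the
sphericity index are invariant under a global rescaling of the five
lengths; WTR is not, because $t_V$ is nonlinear in $r$ — the test suite
checks both facts.

### Sphericity screen

The spherical-shell model only applies to near-spherical, single-lobed
lesions, so cohorts are screened by
$\frac{|h - w|}{h + w} < 0.2$
with a **strict** inequality: a record exactly at 0.2 is excluded, which
is the literal reading of the inclusion rule.

### Post-rupture height correction

Longitudinal comparisons of pre- and post-rupture imaging have found
height on average 14.9% larger after rupture, with width and neck size
unchanged. Since ruptured aneurysms are measured post-rupture, their
measured heights are treated as overestimates of the pre-rupture state:
$h' = h/1.149$. The corrected panel (WTR′, AR′, SR′) therefore applies
$h'$ **to ruptured records only** — the correction un-inflates
post-rupture measurements; unruptured heights are never touched. BF does
not involve height and is never corrected. For SR′ we substitute
literally, $SR' = \max(h', w)/2r$; when the width dominates both heights
this leaves SR unchanged, which matches the observation that the
corrected and uncorrected size-ratio analyses coincide in practice. For
any ruptured record the directions are provable: WTR′ > WTR, AR′ < AR,
SR′ ≤ SR.

## Statistical layer

* **ROC and AUC.** `auc_midrank()` is the midrank Mann–Whitney estimate
  (ties count one half), identical to the trapezoidal area under the
  empirical ROC; the tests compare it against a brute-force pairwise
  oracle on small instances and against an independent ROC
  implementation. WTR-family indices are oriented `lower_is_ruptured`
  (they are negated internally), AR/BF/SR `higher_is_ruptured`, so AUCs
  above 0.5 are comparable across the panel. Confidence intervals use the
  DeLong covariance by default, with a seeded stratified bootstrap (2000
  resamples) available for sensitivity analysis — the two agree within
  0.03 at n = 200 in the test suite. The original analysis does not name
  its interval method, so exact agreement with published intervals is not
  promised.

* **Cutoffs.** The selection rule behind published cutoffs is not stated,
  so the pipeline reports the Youden-optimal cutoff (maximising
  sensitivity + specificity − 1; ties broken toward higher sensitivity,
  then the smaller cutoff; the midpoint of the separating gap is
  reported) *and* evaluates any user-supplied cutoff, so published
  thresholds such as WTR = 1.49e-2 can be assessed directly. The positive
  call is inclusive: score ≤ cutoff for `lower_is_ruptured`.

* **Likelihood ratios.** $LR^+ = \text{sens}/(1-\text{spec})$ with the
  Simel log-method interval,
  $\exp(\ln LR \pm 1.96\sqrt{(1-\text{sens})/tp + \text{spec}/fp})$. A
  zero confusion cell triggers a flagged 0.5 continuity correction.
  Specificity of 1 yields `Inf` with a warning rather than an error.

* **Logistic regression.** Single-predictor fits use iteratively
  reweighted least squares with convergence declared when the largest
  coefficient change drops below $10^{-8}$ (at most 100 iterations).
  Perfect separation is detected both deterministically (disjoint class
  supports) and by coefficient divergence (|coefficient| beyond $10^3$),
  and raised as an error. Fits are cross-checked against `glm` in the
  tests; `glm` is never the implementation, so the package's fit and the
  reference fit remain independent routes. The **critical value** at
  probability $p$ is $(\mathrm{logit}(p) - \beta_0)/\beta_1$, i.e.
  $-\beta_0/\beta_1$ at $p = 0.5$ — the quantity compared against the
  theoretical $6.1\times10^{-3}$ via
  `percent_difference(reference, computed)`, whose denominator is the
  cohort-calculated value (the convention that reproduces the published
  23% figure). Odds ratios per increment are reported as magnitudes,
  $\exp(|\beta_1|\delta)$: published reports quote the OR per 0.001 as a
  number above 1 even though the fitted slope on WTR is negative, and the
  direction of association is carried by the slope's sign. The published
  corrected-model difference of 1.4% is not recoverable from the printed
  rounded coefficients ($0.298/48.3 \to 6.17\times10^{-3} \to 1.1\%$),
  presumably because it was computed from unrounded internal values; the
  package reports what it computes.

* **Group comparisons.** Welch (heteroscedastic) t-tests with
  Satterthwaite degrees of freedom for the continuous measurements, and
  Pearson chi-squared **without** continuity correction (matching common
  spreadsheet behaviour) for site, modality and the dichotomous
  covariates, with missing covariates excluded pairwise. No
  multiple-testing adjustment is applied; $\alpha = 0.05$ throughout.

## The synthetic cohort generator

Patient-level measurements behind the validation study are not publicly
deposited, so `generate_cohort()` produces cohorts with the statistical
structure the analysis assumes — making every downstream stage testable —
while making no claim to match the study's actual distributions:

* **Morphometry.** Lognormal laws with defaults median $h$ = 6 mm (geometric
  SD 1.4), neck geometric-mean diameter 4 mm (GSD 1.3), parent radius
  1.3 mm (GSD 1.25, resampled above 3.9 mm so every record passes the
  $t_V$ validity guard). These are plausible mm-scale values for aneurysms
  of the basilar terminus and communicating arteries; the study's summary
  table is not available to anchor them, and they are fully configurable.
* **Width coupling.** $w = h(1+u)$, $u \sim U(-0.18, 0.18)$, so the
  sphericity index never exceeds 0.099 and the screen retains every
  generated record (even after rupture inflation, where the maximum
  attainable index is 0.167).
* **Neck ellipse.** The drawn geometric-mean diameter is split into
  $d_1 \ge d_2$ with axis ratio uniform on [1, 1.5], preserving the
  geometric mean.
* **Labels.** Each record's (uncorrected) WTR enters
  $P(\text{ruptured}) = \mathrm{logistic}(\beta_0 + \beta_1\,\mathrm{WTR})$
  with the published all-site fit (0.577, −72.8) as default. Two sampling
  modes exist: the default fills configured group sizes (52/28) by
  rejection, mirroring a pre-stratified case–control design; passing
  `n_total` samples prospectively at the natural label frequency. The
  prospective mode exists because fixed group fractions shift the
  recoverable intercept (by the log of the sampling-odds ratio), which
  would confound parameter-recovery experiments — those use `n_total`.
* **Rupture inflation.** Optionally (default on), heights of ruptured
  records are multiplied by 1.149 *after* label assignment, so recorded
  measurements emulate post-rupture imaging and the height correction
  recovers the pre-inflation values exactly (to 1e−12 in the tests).
* **Covariates.** Site (0.6375/0.1875/0.175 across BT/Acom/Pcom), smoking
  (80%) and hypertension (78.75%) are drawn independently of morphometry,
  matching the reported marginal frequencies; the study found no
  significant covariate–rupture associations, and no correlation
  structure is modelled.

All draws flow from one RNG stream seeded by `config$seed`, in documented
order, so cohorts are bit-reproducible.

**What the generator does not emulate:** measurement error and
inter-rater variability, modality-specific measurement bias,
site-specific morphometry or link coefficients, patients contributing
multiple aneurysms, and any covariate–morphometry correlation. Tests that
pass on generated cohorts therefore validate the computational chain and
its statistical behaviour under the assumed model, not the clinical
performance of the indices on real data.

## Numerical and design choices

* All lengths are mm internally and in files; wall thicknesses are
  reported in µm only in human-readable summaries
  (`wall_thickness_at()` converts). CSV outputs keep full double
  precision (round trips are lossless to ≥ 12 significant digits); the
  JSON summary rounds to 3 significant figures for reading.
* The neck axes are canonicalised at read time so $d_1 \ge d_2$; every
  formula is symmetric in the pair, so this only stabilises output.
* When an aneurysm arises partly from two candidate parent vessels, the
  smaller radius is used (the thinner wall dominates rupture
  predisposition); ties between equal radii go to the first-listed
  vessel — a documented reader convention, since no tie rule is
  published.
* Per-site logistic fits use the same IRLS settings as the global fit;
  sites with a single outcome class, too few records, separation or
  non-convergence are flagged in the fit table (`converged = FALSE` with
  a reason) rather than failing the run.
* Analyses treat aneurysms, not patients, as units, consistent with how
  the validation cohort is counted.

## Problem sizes used in the checks

The parameter-recovery experiments use one prospective cohort of
n = 5000 (coefficients recovered within 2 standard errors; critical WTR
within 5%) and 200 prospective cohorts of n = 500 for Wald coverage of
the slope (expected in [0.90, 0.99]) and for the mean recovered critical
value (within 5% of the generating value). Under the default morphometry
the single-cohort critical-value estimate has a relative standard
deviation near 7%, so the 5% single-cohort check is the most
seed-sensitive assertion in the suite; the 200-cohort mean (standard
error ≈ 1.5%) is the robust version of the same question. Null-link
behaviour (AUC ≈ 0.5, non-significant slope) is checked at n = 2000. The
goodness-of-fit of empirical rupture frequency to the link uses
n = 100{,}000 in 20 WTR bins.

## Limitations

The wall-thickness estimate inherits every simplification of the
underlying mechanics: uniform wall thickness, no remodelling, a perfect
sphere, and a vessel-wall law extrapolated from a small intra-operative
series. The package deliberately supports only the three studied sites
(BT, Acom, Pcom) and near-spherical, single-lobed geometry; multilobed
aneurysms, image ingestion, hemodynamic modelling and multivariable risk
scores are out of scope.
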