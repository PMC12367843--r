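# aneurysmorph

Geometric wall-thickness morphometrics and rupture-status analysis for
near-spherical intracranial aneurysms (IAs).

## The problem

Wall thickness is central to aneurysm rupture mechanics but invisible on
routine angiography. For near-spherical IAs, a thin-shell mechanical model
predicts rupture when the **wall-thickness-to-radius ratio (WTR)** falls to
a critical value of 6.1 × 10⁻³. This package is for researchers who want to
estimate WTR from ordinary 2D measurements, compare its discriminative
ability against the classical morphometric indices, and test the
theoretical threshold against cohort data (or, in the absence of shareable
patient data, against configurable synthetic cohorts).

From five per-aneurysm measurements — height *h*, width *w*, perpendicular
neck diameters *d₁*, *d₂*, parent-vessel radius *r*, all in mm — the core
chain is

```
t_V  = (−0.0297 r + 0.1187) · 2r          parent-vessel wall thickness
t_A  = d₁ d₂ / (4 h w) · t_V              dome wall thickness (material conservation)
WTR  = t_A / R_dome ,  R_dome = √(hw)/2   wall-thickness-to-radius ratio
```

alongside aspect ratio `AR = h/√(d₁d₂)`, bottleneck factor
`BF = w/√(d₁d₂)` and size ratio `SR = max(h, w)/2r`. Cohorts are screened
for sphericity (`|h−w|/(h+w) < 0.2`), and a post-rupture height correction
(`h′ = h/1.149`, ruptured records only) yields the corrected panel WTR′,
AR′, SR′. The statistical layer provides midrank AUCs with DeLong or
bootstrap intervals, sensitivity/specificity and positive likelihood
ratios at Youden-optimal or user-supplied cutoffs, IRLS logistic
regression with critical-value inversion (`−β₀/β₁` at P = 0.5), and Welch
t / chi-squared group comparisons. See the methods vignette
(`vignettes/wtr-methods.Rmd`) for assumptions and design choices.

## Worked example

```r
library(aneurysmorph)

# A synthetic cohort with the validation study's design: 52 unruptured /
# 28 ruptured, rupture probability linked to WTR through the published
# all-site logistic model, post-rupture height inflation applied.
coh <- generate_cohort(cohort_config(seed = 42))

# Full analysis, evaluating the published WTR cutoff 1.49e-2.
rep <- run_analysis(coh, analysis_config(cutoffs = list(WTR = 1.49e-2)))
rep
#> Aneurysm rupture-status analysis
#>   80 records analysed (28 ruptured, 52 unruptured); 0 excluded by sphericity screen
#>   AUCs (95% CI):
#>     WTR       0.791 (0.693-0.890)  cutoff 0.0149  sens 96.4%  spec 42.3%  LR+ 1.67
#>     AR        0.833 (0.746-0.920)  cutoff 1.607  sens 78.6%  spec 76.9%  LR+ 3.4
#>     BF        0.754 (0.649-0.860)  cutoff 1.136  sens 96.4%  spec 44.2%  LR+ 1.73
#>     SR        0.723 (0.602-0.843)  cutoff 3.154  sens 50.0%  spec 86.5%  LR+ 3.71
#>     WTR_prime 0.751 (0.644-0.859)  cutoff 0.007318  sens 67.9%  spec 69.2%  LR+ 2.21
#>     AR_prime  0.764 (0.661-0.868)  cutoff 1.619  sens 64.3%  spec 76.9%  LR+ 2.79
#>     SR_prime  0.674 (0.544-0.804)  cutoff 2.816  sens 50.0%  spec 80.8%  LR+ 2.6
#>   fitted critical WTR = 0.00474; theoretical threshold 0.0061 differs by 28.6%
#>   fitted critical WTR_prime = 0.00442; theoretical threshold 0.0061 differs by 38.0%

write_results(rep, "results-dir")   # indices.csv, roc_points_*.csv,
                                    # logistic_fits.csv, summary.json, ...
```

Reading: each row is one index's ROC analysis — the AUC with its 95%
DeLong interval, the evaluated cutoff (user-supplied for WTR here,
Youden-optimal otherwise), and the operating characteristics at that
cutoff. The last lines invert the fitted all-site logistic models at
P = 0.5 and compare the resulting critical values with the theoretical
6.1 × 10⁻³. On a small stratified cohort these fitted critical values are
noisy; inverting the published all-site model directly gives the
reference figure:

```r
critical_value(logistic_model(0.577, -72.8, "WTR"))
#> [1] 0.007925824     # prints as 7.9e-3
```

Measured cohorts enter through `read_cohort("cohort.csv")` (schema
`id,h_mm,w_mm,d1_mm,d2_mm,r_mm,site,ruptured[,modality,smoking,hypertension,vessel_choice]`;
sites BT/Acom/Pcom). A thin command-line wrapper with `run`, `simulate`
and `report` subcommands is installed at `inst/cli/aneurysmorph.R`.

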