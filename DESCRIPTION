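Package: aneurysmorph
Title: Morphometric Wall-Thickness Indices and Rupture-Status Analysis for
    Spherical Intracranial Aneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes geometric wall-thickness estimates and classical
    morphometric indices for near-spherical intracranial aneurysms from 2D
    angiographic measurements.  The central quantity is the
    wall-thickness-to-radius ratio (WTR): parent-vessel wall thickness is
    estimated from a linear thickness-to-diameter correlation, conserved over
    the aneurysm dome surface to yield a dome wall thickness, and normalised
    by the dome radius.  The package screens cohorts for sphericity, derives
    WTR alongside aspect ratio, bottleneck factor and size ratio (with and
    without a post-rupture height correction), and reproduces the
    discrimination analysis: ROC curves with AUC confidence intervals,
    sensitivity/specificity and positive likelihood ratios at chosen cutoffs,
    single-predictor logistic regression with critical-value inversion, and
    comparison against the theoretical rupture threshold of the thin-shell
    mechanical model.  A synthetic-cohort generator with a configurable
    logistic link supports end-to-end testing and parameter-recovery
    experiments without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pROC,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
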