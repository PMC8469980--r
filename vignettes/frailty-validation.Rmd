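---
title: "Validating a brief frailty screen: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a brief frailty screen: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailscreen)
```

## The problem

Frailty in older adults is a transient, potentially reversible state of
reduced physiological reserve that carries excess morbidity and
mortality. Screening for it in primary care needs instruments that are
fast and require no equipment. `frailscreen` implements two such
instruments and the full machinery for validating one against the other
in a diagnostic-accuracy design:

* the **ZFS**, a six-item binary screen (weight loss ≥ 5% over six
  months, monopodal stance < 5 s, living alone, professional aid at
  home, memory complaint, polypharmacy ≥ 5 therapeutic classes). The
  score is the count of "yes" answers; 0 is robust, 1–2 pre-frail, and
  scores at or above a threshold (default 3) are frail.
* the **modified SEGA grid A**, thirteen items each coded 0/1/2 and
  summed to a total out of 26; a total > 8 defines frailty and serves
  as the reference standard. The clinical rubric behind each 0/1/2 code
  is out of scope here: the package consumes pre-coded responses.

## Diagnostic-accuracy machinery

Each screening item, and the screen itself at any cut-point, is crossed
against the reference definition in a 2×2 table (`crosstab()`,
`ctab2x2()`), from which `diag_metrics()` computes sensitivity
tp/(tp+fn), specificity tn/(tn+fp), predictive values, and the Youden
index Se + Sp − 1. Proportions are stored as fractions and rendered as
whole percentages only at the report layer, matching the display
precision such studies print. A zero denominator makes a metric an
explicit flagged `NA`, never a silent zero, so batch reports over many
items cannot be poisoned by one degenerate stratum.

Effect sizes are **risk ratios** — the risk of frailty among item
positives over the risk among item negatives — with Katz log-method
intervals (`rr_ci()`): the published effect measures for all six items
match this formula exactly, which is why it is canonical here rather
than the odds ratio. Association p-values (`association_p()`) use
Fisher's exact test (two-sided, point-probability rule) whenever any
expected cell count is below 5 and the Yates-corrected chi-square
otherwise; this rule is inferred from reproducing the published
p-values on both sides of the expected-count boundary, and the method
applied is always recorded next to the value. Proportion intervals are
Wilson score intervals; the published tables print no intervals for
these metrics, so reports label them as an extension.

## ROC analysis on an integer score

For an integer score the empirical ROC curve has one operating point
per cut-point c, the test being positive iff score ≥ c
(`cutpoint_table()`). The AUC is computed twice — as the tie-corrected
rank statistic P(score~frail~ > score~non-frail~) + ½ P(equal) and as
the trapezoidal area under the ROC polygon — and the two are asserted
equal to 1e−12 before the value is returned. They are mathematically
identical on empirical data, so any disagreement would expose an
off-by-one in the cut-point sweep. The optimal cut-point maximizes the
Youden index, with ties broken toward the lower cut-point: for a
screening instrument, sensitivity is the priority.

Published ROC tables often give only cumulative columns (Se and 1−Sp at
each cut-point). `reconstruct_distribution()` inverts that: it scales
the fractions by the group sizes, requires every scaled count to land
within 0.02 patients of an integer (a guard against mistranscription),
differences adjacent cut-points, and collapses scores at or above the
last cut-point onto that cut-point's value. The collapse is justified
by a cross-table consistency check: the pooled reconstructed scores
reproduce the published cohort mean (2.1) and SD (1.35) at printed
precision. A label of the form "> k" in such tables is read as
"score ≥ k": under that reading the ≥ 1 row reproduces the published
87 screen-positives and the ≥ 3 row the published 36 frail patients,
while a literal strict reading matches neither. This reading is a
deliberate, load-bearing interpretation.

## Correlations

`pearson_r()` is the product-moment correlation; on 0/1 indicators it
equals the phi coefficient, and on 0/1/2 codes the plain ordinal
correlation — the only reading under which near-duplicate item pairs
across the two scales can reach correlations around 0.9.
`item_matrix()` produces the 6 × 13 cross-scale matrix with the
total-score correlation and its Fisher-z interval
(tanh(atanh r ± z/√(n−3))) attached. Constant columns yield flagged
`NA` entries rendered with an explicit sentinel, because printing 0
would fabricate independence. No tetrachoric or polychoric estimation
is attempted.

## The synthetic-cohort generator

No raw patient data are deposited for this design, so end-to-end
testing uses `generate_cohort()`: a single latent frailty factor
f ~ N(0,1) per patient, plus one shared residual per "twin pair" of
near-duplicate items across the scales (weight loss–nutrition, home
aid–provenance, memory–cognition, polypharmacy–medications,
balance–mobility, lives alone–provenance). Item i's latent is
λ~i~ f + Σ ρ w~pair~ + residual, scaled to unit variance; binary items
fire above qnorm(1 − p~i~), ordinal items are cut at two quantiles, so
every marginal prevalence is matched by construction regardless of the
correlation structure. A full 19 × 19 target correlation matrix is not
identifiable from published summary tables, and this one-factor-plus-
pairs structure is the simplest that jointly reproduces (a) the item
prevalences, (b) twin-pair dominance within each row of the item
matrix, and (c) a high total-score correlation.

Sampling follows a fixed documented order — factor, pair residuals,
items, demographics, each as a block of n draws under one seeded
generator — so equal specifications generate byte-identical cohorts and
appending an item never perturbs earlier columns.

**Calibration.** The free parameters (loadings λ, couplings ρ, ordinal
category probabilities) were tuned once with
`scripts/calibrate_sim.R` at n = 20 000 and then frozen in
`default_spec()`. The frozen defaults give a total-score correlation of
about 0.79 (goal 0.81 ± 0.08) and a reference-frail prevalence of about
22% (goal 19.6 ± 5 points). Known limitation: under a one-factor
copula, loadings high enough to push the totals correlation near 0.81
inflate the reference total's spread (simulated SD ≈ 4.6 versus the
published 3.11); the two goals are jointly unattainable in this family,
and the correlation goal was given priority. Demographics are sampled
independently of the factor except age (loading 0.35, reflecting that
frailty rises with age, consistent with the published age-row
correlations of roughly 0.2–0.5) and the medication count, which is
driven by the polypharmacy item's latent so that the printed medication
mean (4.3 ± 3.0) stays consistent with the polypharmacy prevalence.

What passing simulator-based tests shows is therefore structural — the
scoring, accuracy, ROC and correlation code behaves correctly on
cohorts with realistic marginals and a plausible dependence skeleton —
not that the generator replicates the real cohort's full joint
distribution; individual entries of the published item-correlation
matrix are sample values at n = 102 and are matched only qualitatively.

## Numerical and interface choices

* Problem sizes in the test suite: exhaustive oracles (hypergeometric
  enumeration, brute-force pair counting) run at n ≤ 60; simulator
  recovery checks at n = 10^4^ with 3-binomial-SE bands; the dual-AUC
  identity over 10^3^ random distributions. All are desk-scale.
* Missing scale answers are rejected, not imputed: partial
  administration of either instrument is undescribed and a six-item
  screen prorated from five answers is a different instrument.
* Decimal commas in transcribed tables are normalized at the fixtures
  layer only; numerics never see locale-dependent text.
* Cohort files are comma-separated with dot decimals; binary items
  serialize as 0/1, and the reader also normalizes yes/no and oui/non
  case-insensitively.
* The command line (`fs_cli()`, installed script `inst/cli/frailscreen.R`)
  returns 0 on success, 1 on usage errors, 2 on validation failures,
  and 3 when an analysis completes but contains degenerate strata.

## A worked reconstruction

```{r}
sizes <- roc_group_sizes()
dist <- reconstruct_distribution(table9_rows(),
                                 n_pos = sizes[["n_pos"]],
                                 n_neg = sizes[["n_neg"]])
dist
auc(dist)
curve <- cutpoint_table(dist)
optimal_cutpoint(curve)
subset(as.data.frame(curve), cutpoint == 3)
```

```{r}
cohort <- generate_cohort(default_spec(n = 500, seed = 42))
report <- validation_report(cohort)
report$roc$auc
report$correlation$r
```
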