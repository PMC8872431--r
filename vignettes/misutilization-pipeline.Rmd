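---
title: "Forensic assessment of hospital resource misutilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic assessment of hospital resource misutilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misutilizr)
```

## The problem

Hospitals often cannot judge whether an expensive resource — here, a CT
scan of the pelvis/abdomen without contrast during an in-patient stay —
was used appropriately, because clinical markers (PSA, Gleason score,
tumour stage) are missing from administrative claims. `misutilizr`
implements a forensic alternative that needs only administrative data:

1. **Risk adjustment.** A multivariate logistic regression predicts the
   probability that the outcome resource is used in a visit, from
   patient characteristics (age group, race, payor, admission source,
   discharge status, comorbidity flags, length of stay) and from the
   seven *competing imaging resources* used during the same visit
   (other CTs, X-rays, MRI/MRA, ultrasound, special imaging, nuclear
   medicine, miscellaneous imaging). Competing-resource usage is the
   distinctive covariate block: visits consuming alternative imaging
   carry information about how likely the outcome CT is under common
   practice. Three covariate sets are compared — (a) patient +
   resources, (b) patient only, (c) resources only — with AUCs and a
   paired DeLong test for (a) vs (b).
2. **Decision threshold.** A decision-curve analysis computes the net
   benefit of flagging visits with fitted probability `p >= t`,
   `NB(t) = TP/n - FP/n * t/(1-t)`, against treat-all and treat-none
   policies. Within the threshold range where the model adds value, the
   working threshold is *calibrated to industry intensity*: it is the
   grid value whose flagged rate is closest to the observed utilization
   rate, so the classification neither inflates nor deflates
   utilization relative to industry standards. A threshold `t` encodes
   a `t : (1-t)` cost:benefit tradeoff (0.20 is 1:4, with cost relating
   to under-utilization).
3. **Visit labels.** A visit is *over-utilized* if the resource was
   used while `p < t`, *under-utilized* if unused while `p >= t`,
   otherwise concordant. The misutilization rate decomposes exactly
   into over plus under components.
4. **Disparities.** Per-characteristic logistic models of the under-
   (over-) utilization indicator give odds ratios with Wald 95%
   intervals (forest-plot ready).
5. **Facility profiling.** Under a null of one common per-visit rate,
   each facility's misutilization count is Poisson with mean
   `pooled rate x volume`; facilities with exact one-sided upper-tail
   `p < 0.01` are flagged, ranked, and summarised with bubble plots and
   log-volume regressions.

Because the motivating all-payor claims database is proprietary, the
package ships a first-class synthetic cohort generator that reproduces
the statistical structure the analysis assumes, with known ground
truth, so every stage is testable end to end.

## The synthetic cohort

Defaults emulate the motivating cohort's conditions: 51,111 visits
across 1056 facilities, the published categorical marginals (counts
over 51,111), competing-resource prevalences, a mean length of stay of
4.57 days (SD 5.44, gamma), and an 11.72% marginal outcome rate.

* **Facility volumes** are log-normal (`sdlog = 1` by default; only
  the direction of the skew is pinned down by the setting being
  emulated, so a unit log-SD — a typical skew for US facility
  volumes — was chosen once) and then
  allocated by a multinomial so volumes are integers, at least 1, and
  sum exactly to the target.
* **Competing resources** come from a Gaussian copula: a latent
  7-variate normal with the configured correlation matrix, thresholded
  at the quantiles of the marginal prevalences. This makes the latent
  correlations exactly the tetrachoric correlations of the bits —
  the quantity the analysis estimates — while preserving marginals.
  The default exchangeable correlation of 0.3 reflects the moderate
  positive co-usage expected of imaging modalities.
* **The outcome** follows a true logistic model. The default
  coefficients are moderate case-mix effects plus stronger positive
  competing-resource effects; the intercept (−3.3403) was calibrated
  once by large-n Monte Carlo so the marginal outcome rate matches the
  11.72% industry intensity.
* **Planted outliers** multiply (mode `over`) or divide (mode `under`)
  a facility's outcome odds, leaving case mix untouched — so planted
  misutilization is behaviour, not patient mix, mirroring the
  risk-adjustment logic. With `outlier_plan = NULL` the default plan
  plants 12 over- and 8 under-utilizers at odds multiplier 3 among
  facilities with at least 100 visits; `list()` disables planting.
* **Covariate clustering**: covariates are drawn i.i.d. within and
  across facilities. Real facilities differ in case mix; nothing in
  the source data quantified that clustering, so the generator
  defaults to none (configurable through `covariate_marginals`).

What passing tests on this cohort do *not* show: robustness to
facility-level case-mix confounding, miscoded claims, informative
missingness, or non-logistic outcome mechanisms. The generator is
well-specified by construction; results on real claims depend on how
far those assumptions hold.

## Category collapsing

The ingest rules mirror standard low-count pooling for claims tables:

* payors `charity` and `indigent` merge into one level;
* age-group levels lying wholly at or below 45 merge into the youngest
  category (levels straddling the bound, like 46–50, are left alone);
* discharge-status levels with share strictly below 0.1% pool into
  `other` (a level at exactly 0.1% is kept — the rule is strict);
* comorbidity flags and MS-DRG levels need at least 500 visits
  (inclusive) to stay; rarer MS-DRGs pool into a catch-all level,
  rarer flags leave the covariate set.

Collapsing is idempotent, and every action is recorded in a report
(`collapse_report()`).

Reference levels for dummy coding are white race and traditional
Medicare (the conventional comparison groups for these variables), and
the modal level elsewhere. Length of stay enters untransformed: it is
a right-skewed exposure-like covariate, and keeping it linear on the
log-odds scale keeps the coefficient interpretable per day; a log
transform is a one-line change in `build_design()` if preferred.

## Numerical choices

* **Logistic fits** use iteratively reweighted least squares
  (`stats::glm.fit`) with a tightened deviance tolerance (1e-10) so
  the score equations hold to `max |X'(y - p)| < 1e-6`. Quasi-complete
  separation (|coefficient| > 15) triggers a warning and clears the
  `converged` bit; on small cohorts rare payor/admission levels can
  legitimately trip this.
* **AUC machinery** is the DeLong placement-value construction:
  the AUC equals the Mann–Whitney statistic with ties counted ½ and is
  checked against an O(n²) pair-counting oracle; paired differences
  use the covariance of structural components. Intervals are normal
  theory, truncated to [0, 1].
* **Tetrachoric correlations** are maximum likelihood under the
  bivariate-normal liability model: thresholds fixed at the margins'
  normal quantiles, correlation by 1-D likelihood search over
  [−0.999, 0.999] (not the cosine approximation, so estimates can be
  validated against the copula simulation). Empty margins return a
  flagged undefined estimate.
* **Pattern chi-square** is Pearson's, over *observed* patterns only
  (unobserved combinations of the 128 possible contribute no cells),
  no continuity correction; low expected counts are reported, not
  fatal.
* **Decision grid** is 0.001 steps over (0, 0.99]; published threshold
  ranges are reported to two decimals, so a millesimal grid
  over-resolves them. Visits exactly at the threshold count as
  expected use (`>=`); the tie direction is declared, not inferable
  from the source.
* **Facility tests** use the exact Poisson upper tail
  `P(X >= c)` via `stats::ppois` (upper regularized incomplete gamma),
  valid at small volumes where a Wald z on a per-facility GLM would
  not be. The pooled rate includes the facility under test by default
  (`leave_one_out = TRUE` available); flagging uses raw `p < 0.01`
  (Benjamini–Hochberg behind `adjust = "BH"`). Volume enters
  regressions as the natural log.
* **Odds ratios** default to unadjusted single-characteristic models,
  matching the tabular presentation convention; a covariate-adjusted
  variant is behind `adjusted = TRUE` since the convention is
  ambiguous. The "under" denominator is all visits (not just unused
  ones) so over- and under-utilization ORs are comparable.

## Problem sizes used in the tests

The suite exercises Monte-Carlo claims at sizes chosen to make the
binomial error bands decisive while keeping the suite quick to run:
marginal fidelity and threshold calibration at 50,000 visits; outcome
rate recovery at 200,000; tetrachoric copula recovery at 100,000;
coefficient recovery over 20 replicate 50,000-visit cohorts (≥95% of
coefficients within 3 standard errors); planted-outlier recovery over
50 replicates of 1000 null facilities plus 10 planted 3×-rate
facilities (sensitivity ≥80%, null flag rate ≤2% at `p < 0.01`). The
outlier replicates simulate per-facility label counts directly — the
flagging stage consumes only counts and volumes, so replicating the
upstream model fit would add cost without adding evidence.

## Known limitations

* Misutilization is defined against *industry-average* behaviour, not
  clinical appropriateness; a cohort-wide practice shift moves the
  benchmark with it. An industry-leaders reference is supported via
  `target_rate` in `calibrate_threshold()`.
* No hierarchical shrinkage of facility rates: small facilities rely
  on the exact tail's conservatism rather than partial pooling.
* Odds ratios are associations; socioeconomic confounders absent from
  administrative data are not adjusted for.
* The exploratory classification-tree view of resource combinations is
  out of scope; the pattern table, chi-square, and tetrachoric network
  quantities cover the co-usage analysis.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)
bundle <- run_pipeline(synthetic_config = cfg, outdir = "report")
bundle$summary
bundle$auc_comparison$aucs
dplyr::filter(bundle$facility$flags, flagged)
```
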