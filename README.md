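# misutilizr

Forensic assessment of hospital resource misutilization from
administrative claims data.

Hospitals frequently lack the clinical markers (e.g. PSA levels,
Gleason scores) needed to judge whether an imaging resource was used
appropriately. `misutilizr` implements a purely administrative
alternative, demonstrated on the use of CT scans of the pelvis/abdomen
without contrast during in-patient visits of a prostate-cancer cohort:

1. **Risk adjustment** — a multivariate logistic model for the
   probability `p_i` of outcome-resource use per visit, built from
   patient characteristics **and** seven competing imaging resources
   (other CTs, X-ray, MRI/MRA, ultrasound, special imaging, nuclear
   medicine, miscellaneous), with AUC comparison of the covariate sets
   (a) patient + resources, (b) patient only, (c) resources only via
   DeLong's test for correlated ROC curves.
2. **Decision-curve threshold** — net benefit
   `NB(t) = TP/n − FP/n · t/(1−t)` against treat-all/treat-none; the
   working threshold is calibrated so the flagged rate
   `P(p_i ≥ t)` matches the industry-average utilization intensity.
3. **Visit classification** — *over-utilized*: used with `p_i < t`;
   *under-utilized*: unused with `p_i ≥ t`; misutilization rate
   = over + under.
4. **Disparities** — odds ratios (Wald 95% CI) of under-/over-
   utilization by patient characteristics such as race.
5. **Facility profiling** — volume-adjusted exact Poisson rate tests
   under a common-rate null (`X_f ~ Poisson(λ̂ · v_f)`,
   `λ̂ = Σc_f / Σv_f`), flagging facilities with one-sided upper-tail
   `p < 0.01`, plus log-volume regressions and ranked extreme tables.

Because the motivating all-payor database is proprietary, the package
includes a synthetic administrative-cohort generator (Gaussian-copula
competing resources, log-normal facility volumes, a ground-truth
logistic outcome model, planted outlier facilities) whose defaults
emulate the study conditions: 51,111 visits across 1056 facilities
with an 11.72% outcome utilization intensity.

## Worked example

```r
library(misutilizr)

cfg <- synthetic_config(seed = 1)            # 51,111 visits, 1056 facilities
bundle <- run_pipeline(synthetic_config = cfg)

bundle$auc_comparison$aucs
#> # A tibble: 3 × 4
#>   covariate_set   auc conf.low conf.high
#>   <chr>         <dbl>    <dbl>     <dbl>
#> 1 a             0.708    0.701     0.715
#> 2 b             0.621    0.614     0.629
#> 3 c             0.671    0.664     0.678

bundle$decision$calibration
#> threshold 0.224 (cost:benefit odds 0.289); flagged rate 0.1227 vs target 0.1222

bundle$summary[, c("mis_rate", "over_rate", "under_rate")]
#> # A tibble: 1 × 3
#>   mis_rate over_rate under_rate
#>      <dbl>     <dbl>      <dbl>
#> 1    0.170    0.0846     0.0851
```

Reading: the full model (set *a*, AUC 0.708) separates users from
non-users better than patient characteristics alone (*b*) or competing
resources alone (*c*), showing the explanatory value of the
competing-resource block. Calibration picks the threshold whose
flagged intensity (12.3%) best matches the cohort's observed
utilization (12.2%), and at that threshold 17.0% of visits are
misutilized, split roughly evenly between over- and under-utilization.
Facility flags, odds-ratio tables, the decision curve, and ranked
extreme facilities are in `bundle$facility`, `bundle$odds_ratios`, and
`bundle$decision`; `outdir =` writes every table as CSV/JSON with a
manifest, and `figures = TRUE` adds the standard plots
(`autoplot()` on the decision curve, `plot_forest()`,
`plot_facility_rates()`, `plot_flagged_bubbles()`,
`plot_volume_flag_comparison()`, `plot_under_over()`).

Fitted models support `tidy()`, `glance()`, and `augment()`.

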