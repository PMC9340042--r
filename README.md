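# rdrisk

External validation of risk-prediction models for progression to
**referable diabetic retinopathy (RDR)** in longitudinal screening cohorts.

Diabetic eye-screening programmes photograph the retina annually and refer
patients whose disease has progressed to a referable stage. Because annual
screening of everyone with type 2 diabetes is increasingly unaffordable,
prognostic models are used to stratify risk and personalise screening
intervals: a survival-based score over systemic covariates, and
grade-category scores built from one or two consecutive retinopathy
gradings. `rdrisk` provides the full machinery needed to validate such
models against a screening programme's records:

- **Grading logic** — the English screening-programme R/M scale
  (R0–R3, M0/M1), the RDR outcome (M1 or R ≥ 2 in either eye), and the
  two-screening risk groups A–I (with B/C, apparent regression of mild DR,
  excluded by design).
- **Cohort construction** — index screening (the second recorded episode),
  systemic-visit linkage (latest complete visit within 180 days before
  index), inclusion rules, follow-up and event status, with a fully
  audited exclusion tally.
- **Risk-score engines** — configurable coefficient sets (YAML/JSON):
  survival scores `100·[1 − S(t+Δt)/S(t)]` with
  `S(t) = S₀(t)^exp(β'x)` (exponential, Weibull or tabulated `S₀`;
  Δt = 1 month), and grade-category linear scores in three variants.
- **Validation statistics** — cumulative/dynamic time-dependent ROC AUC
  with inverse-probability-of-censoring weights from a reverse
  Kaplan–Meier estimate, standard full-period ROC AUC, percentile
  bootstrap confidence intervals, and risk-stratified referral-rate
  tables (per 1000 person-years, by score quintile or risk group).
- **A synthetic cohort generator** — seeded, with known ground-truth risk
  structure, emulating the structure of a systematic screening programme
  (annual screening, 4-monthly systemic visits, staggered enrolment,
  grade regression, censoring), so every pipeline stage is testable
  without access to patient data.

All user-facing functions take data frames and return tibbles; results
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(rdrisk)

sim    <- simulate_cohort(generator_config(n_patients = 939, seed = 1))
cohort <- build_cohort(sim$patients, sim$screenings, sim$visits)
followup_summary(cohort)
#> # A tibble: 1 × 6
#>       n person_years events median_followup min_followup max_followup
#>   <int>        <dbl>  <int>           <dbl>        <dbl>        <dbl>
#> 1   697        2166.     42            3.01        0.816         5.21
exclusion_tally(cohort)
#> # A tibble: 4 × 2
#>   reason                 n
#>   <chr>              <int>
#> 1 TOO_FEW_SCREENINGS   165
#> 2 INELIGIBLE_GRADES     15
#> 3 RISK_GROUP_BC         54
#> 4 NO_SYSTEMIC_MATCH      8
```

Of 939 simulated patients, 697 enter the analysis cohort; they contribute
2166 person-years and 42 referrals over a median 3.0 years of follow-up.
The exclusion tally mirrors the cohort-flow diagram a validation study
would report: too few screenings, ineligible grades at the first two
screenings, the excluded regression groups B/C, and failed systemic
linkage.

```r
res <- run_validation(
  sim$patients, sim$screenings, sim$visits,
  models = list(
    icelandic   = list(coefs = example_coefficients("icelandic"), engine = "icelandic"),
    grades_only = list(coefs = example_coefficients("gloucester_two_grades"),
                       engine = "TWO_GRADES_ONLY")
  ),
  horizon = 2, n_boot = 100, seed = 1
)
tidy(res)
#>   model       model_id  engine  method   horizon   auc ci_lower ci_upper
#> 1 icelandic   icelandi… icelan… tdroc_i…       2 0.591    0.485    0.700
#> 2 icelandic   icelandi… icelan… roc_ful…     Inf 0.668    0.583    0.745
#> 3 grades_only glouces…  TWO_GR… tdroc_i…       2 0.514    0.432    0.629
#> 4 grades_only glouces…  TWO_GR… roc_ful…     Inf 0.474    0.433    0.540
```

Each model gets a 2-year time-dependent AUC and a full-period AUC, each
with a 100-resample percentile bootstrap CI. (The shipped coefficient
sets are *synthetic illustrations* of the model structures — see
`?example_coefficients` — so their discrimination here reflects the
generator's data-generating process, not any published model's quality:
the survival score tracks the covariates that truly drive risk in the
default generator, while the grade-only score does not.)

`res$models$grades_only$rate_table` is the risk-group referral-rate table
(A dominates, rates per 1000 person-years per group);
`quintile_table()` produces the analogous score-quintile table, splitting
939 records into strata of 188/188/188/188/187. `autoplot(res)` overlays
the ROC curves.

A thin command-line wrapper with `simulate` and `validate` subcommands is
installed at `system.file("cli", "rdrisk.R", package = "rdrisk")`.

## Vignette

`vignettes/validating-rdr-risk-models.Rmd` documents the statistical
methods, the generator's assumptions and calibration, numerical
conventions, and known limitations.
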