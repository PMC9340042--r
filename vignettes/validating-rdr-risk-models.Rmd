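---
title: "Validating risk-prediction models for referable diabetic retinopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating risk-prediction models for referable diabetic retinopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdrisk)
```

## The problem

Systematic diabetic eye screening photographs both retinas of everyone
with diabetes, typically once a year, and refers patients whose disease
reaches a *referable* stage: maculopathy (M1), pre-proliferative (R2) or
proliferative (R3) retinopathy in either eye. Most screened patients have
no or only mild background retinopathy and a very low short-term risk of
progression, so programmes increasingly want risk-stratified screening
intervals. That requires prognostic models — and before a model can set
anyone's screening interval it must be validated externally: scored on a
cohort it was not developed on, with its discrimination and stratified
referral rates measured honestly under censoring.

`rdrisk` implements that validation pipeline end to end, together with a
synthetic cohort generator so the whole pipeline is testable without
patient data.

## Grading, outcome and risk groups

Grades follow the English screening-programme scale: per eye, retinopathy
R0 (none), R1 (mild/background), R2 (pre-proliferative), R3
(proliferative), and maculopathy M0/M1. Conventions the scale itself does
not settle are fixed explicitly:

* **RDR** (`screen_rdr()`) is M1 at any R level, or R ≥ 2, in either
  gradable eye. The unusual combination R0M1 is treated as referable:
  maculopathy triggers referral regardless of the R grade.
* An **ungradable eye** is missing in both its R and M columns — never
  coded R0M0. An episode with one gradable eye can still be assessed for
  RDR (the gradable eye decides), but risk-group classification requires
  both-eye status, so such episodes are ineligible for it. An episode
  with no gradable eye is an error unless the caller opts into `NA`.

The two-screening **risk groups** (`classify_risk_group()`) come from the
per-episode DR category — `NO_DR` (both eyes R0M0), `MILD_ONE_EYE`,
`MILD_BOTH_EYES`, `OTHER` (anything involving R ≥ 2, M1 or an ungradable
eye) — crossed over the first two screenings:

| first \ second | NO_DR | MILD_ONE_EYE | MILD_BOTH_EYES |
|---|---|---|---|
| NO_DR          | A | D | G |
| MILD_ONE_EYE   | B | E | H |
| MILD_BOTH_EYES | C | F | I |

Any `OTHER` at either screening makes the patient `INELIGIBLE`. Groups B
and C — mild DR at the first screening apparently regressing to none at
the second — are defined but flagged `excluded`: the screening-only grade
model carries no coefficient for them, so no risk prediction exists and
they are removed from the cohort. A brute-force enumeration of all 64 × 64
two-eye grade combinations at two screenings (tested) shows the mapping is
exhaustive, assigns exactly one label each, reaches all of A–I, and is
invariant to swapping the eyes.

## Cohort construction

Eligibility needs **at least three screening episodes**: the first two
define the risk group, the second is the *index* screening at which
follow-up starts, and later episodes determine the outcome. Later grades
never change the index choice. Systemic covariates are linked from the
most recent visit at or before the index date, no older than 180 days
(configurable), at which all required variables (HbA1c, total
cholesterol, systolic BP by default) were measured; the window was read
as applying to every candidate visit, not only the immediately preceding
one, because that is the reading under which the stated rule ("latest
complete prior visit") remains well defined.

Follow-up runs from the index date to the first post-index episode
satisfying the RDR definition (event) or to the last recorded episode
(censored). Progression is only observable at screenings, so the
screening date is the operational event date. Post-index episodes with no
gradable eye cannot reveal RDR and are skipped for event detection, but
the last of them still anchors censoring. Conventions: years are days /
365.25 everywhere; diabetes duration at index is floored at 0 (a patient
may be diagnosed at entry). Every exclusion is logged per patient and
tallied per reason (`exclusion_tally()`), and `write_cohort()` emits the
tally as a JSON sidecar so the cohort flow stays auditable. Construction
is deterministic and invariant to input row order (tested).

## Risk-score engines

Coefficient sets are **external configuration**, not code: the published
coefficient tables of the models this machinery is designed to validate
are not redistributed, so the package ships clearly labelled synthetic
illustrative sets (`example_coefficients()`) that reproduce the models'
*structure* — variables, baseline-survival family, grade-category terms —
with made-up values. The validation machinery, not any particular
coefficient vector, is the reusable content.

The **survival score** is the approximate one-month conditional hazard at
the index screening, on the time-since-diagnosis scale $t$:

$$\mathrm{score} = 100\,\Big[1 - \frac{S(t+\Delta t)}{S(t)}\Big],
\qquad S(t) = S_0(t)^{\exp(\beta' x)} .$$

$\Delta t$ defaults to 1/12 year ("one month" interpreted as 1/12 year,
consistent with the annual time scale, not 30 days). The factor 100 puts
the score on a numerically stable scale for ROC analysis. $S_0$ may be
exponential, Weibull, or tabulated (linear interpolation; extrapolation
beyond the last tabulated time is refused rather than guessed). The
default combination is the proportional-hazards power form
$S_0(t)^{\exp(lp)}$; a literal multiplicative mode
$\min\{1, S_0(t)\,e^{lp}\}$ is also available because that phrasing
occurs in the validation literature, but read literally it can exceed 1,
so it is clamped — the power form is the default precisely because it is
the standard survival-model convention. Both modes are tested. With an
exponential baseline and null predictor the score equals
$100\,(1-e^{-\lambda \Delta t})$ exactly (tested to 10+ significant
digits), and under the power form the score ranking equals the
linear-predictor ranking (tested on 1000 random records).

The **grade models** come in three variants: risk group alone (at most 7
distinct scores, one per eligible group), risk group plus HbA1c, total
cholesterol and optionally diabetes duration, and a single (index)
grading category plus HbA1c, cholesterol and duration. Whether the
two-grading systemic variant includes duration is left to configuration —
the term list is config, so either convention can be expressed. Scoring a
B/C record is an error by design, not a silent `NA`.

## Discrimination and rate tables

The **time-dependent ROC** at horizon $\tau$ (default 2 years, a
realistic ceiling for extending screening intervals) uses the
cumulative/dynamic definition: cases are observed events with
$T \le \tau$, controls are subjects still event-free at $\tau$. Censoring
before the horizon is handled by inverse-probability-of-censoring
weighting: cases weighted by $1/\hat G(T_i)$ and controls by
$1/\hat G(\tau)$, with $\hat G$ the reverse Kaplan–Meier estimate of the
censoring survival function (via `survival::survfit`). This estimator was
chosen as the standard, assumption-light default among time-dependent ROC
estimators; its correctness is pinned by the property (tested on hundreds
of random instances) that with no censoring before the horizon it reduces
*exactly* to the Mann–Whitney statistic computed by exhaustive pairwise
comparison, with ties counting one half. A full-period ROC
(`roc_auc_full()`, cross-checked against pROC) treats the event indicator
over the whole follow-up as the label. AUC is invariant under strictly
increasing score transforms (tested).

**Confidence intervals** are percentile bootstrap over whole patients,
100 resamples by default, seed mandatory. Percentile (rather than BCa)
was chosen because only the resample count is specified by the validation
convention being followed; the interval's behaviour is itself measured —
a simulation study over cohorts with analytically known true AUC
(binormal case/control scores, truth $\Phi(1/\sqrt2)$) checks that the
nominal 95 % interval covers in the high-80s-to-high-90s range. If the
statistic is undefined on more than half the resamples the interval is
declared unstable rather than quietly summarised.

**Rate tables** report events per 1000 person-years, rounded half-up to
one decimal (half-up, not banker's, to match how such tables are
conventionally printed). Quintile tables rank ascending by score, split
into five near-equal strata with the larger strata first (939 → 188, 188,
188, 188, 187), and break ties deterministically by patient id. Totals
(n, events, person-years) are conserved across strata (tested).

## The synthetic cohort generator

`simulate_cohort()` emulates the *structure* of a systematic type-2
screening programme: staggered enrolment over 5.5 years of an 8-year
observation window, annual screening with ±21-day jitter, systemic visits
every 4 months with small measurement noise and occasional missingness,
covariates from truncated normals at the modelled cohort's means and SDs
(HbA1c 6.8 (1.2) %, SBP 136 (16.4) mm Hg, BMI 31.1 (6.4) kg/m², age 64
within 30–89, …), a mix of prevalent (46 %, exponential mean 6 y
duration) and newly diagnosed diabetes, and independent dropout.

Two event mechanisms are provided. The default (`event_mode =
"covariate"`) draws a latent exponential time to RDR with hazard
$h_0 \exp(\beta' x)$ — the same proportional-hazards family the survival
engine assumes, so discrimination recovery has a known target and exact
ground truth (`truth$lp_true`, `truth$latent_event_years`). The
deliberately misspecified `"grade_state"` mode instead drives the
interval hazard by the current number of eyes with background DR, for
robustness studies of grade-based scores. Background retinopathy itself
follows a two-state R0↔R1 Markov chain per eye (gain rate 0.14/y,
regression rate 1.1/y, initial per-eye prevalence 8 %) with a 0.4
probability that both eyes share a transition draw — between-eye
correlation leaves the per-eye marginals unchanged but makes bilateral
disease, and hence groups C, F, G, H, I, realistically frequent. RDR
manifests at the first screening on or after the latent time (R2 in one
eye, maculopathy in half the cases), after which the patient leaves the
programme, exactly as a referred patient would.

Default rates were calibrated once, against the emulated programme's
published headline figures and before any acceptance measurement, so that
a 939-patient draw yields ≈ 40 events in the eligible cohort, a median
follow-up of ≈ 3 years, a cohort dominated by group A, and a nonzero flow
into the excluded groups B/C; they are study conditions, not tuning
knobs. Two published figures cannot be hit simultaneously at `n_patients
= 939` — an *eligible* cohort of 939 and 40 events among eligibles —
because enrolment losses precede eligibility; the generator keeps the
event-count target and accepts a smaller eligible cohort (≈ 700).

What the generator does **not** emulate: real disease biology (DMO vs PDR
pathways, treatment), attendance behaviour, covariate drift over time
(values are baseline plus noise), grade–covariate dependence in the
default mode, and calendar effects. Passing tests therefore demonstrate
that the *pipeline machinery* is correct under a known data-generating
process — not that any particular model is accurate on real screening
data, which is precisely the question an external validation on real
records would answer.

## Simulation-study sizes and tunables

The shipped studies use sizes chosen to characterise the estimators well
while remaining comfortable to rerun: 200 random instances for the
no-censoring oracle equivalence, 2000 samples for the null-discrimination
check, 50 replicate cohorts of 939 patients for discrimination recovery
(strong-effect preset `strong_betas()`, expected true-score AUC well
above 0.70 with the permuted arm at 0.5), and 200 cohorts for bootstrap
coverage. The parameters that matter most in practice, with defaults:
prediction horizon 2 years; bootstrap resamples 100; systemic linkage
window 180 days; $\Delta t$ 1/12 year; all exposed as function arguments,
with the seed explicit everywhere randomness enters.

## Known limitations

* The IPCW estimator assumes censoring independent of score and outcome;
  informative censoring would bias the weighted AUC.
* Events are interval-censored by the screening schedule; anchoring them
  at the detecting screening (the operational referral date) slightly
  overstates event times when screening gaps are long.
* The bootstrap is not stratified on event status; with very few events,
  resamples occasionally contain no cases and are dropped (declared
  unstable past 50 %).
* Shipped coefficient sets are illustrative; validating a real model
  requires supplying its published coefficients and baseline survival as
  configuration.
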