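# Risk-score engines.
#
# The Icelandic-style engine is a survival score: a linear predictor over
# systemic covariates combines with a baseline survival S0(t) on the
# time-since-diagnosis scale, and the score is the approximate one-month
# hazard at the index screening, scaled by 100.  The Gloucester-style
# engines are linear scores over the two-screening risk group (and, in two
# variants, systemic covariates or the single index-screening grade
# category plus diabetes duration).

#' Linear predictor of a coefficient set over cohort records
#'
#' Computes sum(beta_i * f_i(x_i)) over the set's continuous terms, plus the
#' categorical term for each record's level when the set defines one.
#' Deterministic; a missing covariate raises an error naming the variable.
#'
#' @param records Data frame of cohort records (e.g. from [build_cohort()]).
#' @param coefs A [coefficient_set()].
#' @return Numeric vector, one linear-predictor value per record.
#' @export
#' @examples
#' cs <- coefficient_set("demo",
#'   terms = list(list(variable = "hba1c_pct", beta = 0.5))
#' )
#' linear_predictor(tibble::tibble(hba1c_pct = 6.8), cs) # 3.4
linear_predictor <- function(records, coefs) {
  stopifnot(inherits(coefs, "coefficient_set"))
  lp <- rep(0, nrow(records))
  for (term in coefs$terms) {
    x <- fetch_covariate(records, term$variable, coefs$model_id)
    if (term$transform == "log") {
      if (any(x <= 0)) {
        abort(sprintf(
          "Model `%s`: log transform of `%s` requires positive values.",
          coefs$model_id, term$variable
        ))
      }
      x <- log(x)
    }
    lp <- lp + term$beta * (x - term$center)
  }
  if (!is.null(coefs$categorical)) {
    lv <- fetch_covariate(records, coefs$categorical$variable, coefs$model_id,
      numeric = FALSE
    )
    lv <- as.character(lv)
    known <- names(coefs$categorical$levels)
    bad <- setdiff(unique(lv), known)
    if (length(bad)) {
      abort(sprintf(
        "Model `%s` defines no coefficient for %s level(s): %s.",
        coefs$model_id, coefs$categorical$variable,
        paste(bad, collapse = ", ")
      ))
    }
    lp <- lp + unlist(coefs$categorical$levels)[lv]
  }
  unname(lp)
}

fetch_covariate <- function(records, variable, model_id, numeric = TRUE) {
  if (!variable %in% names(records)) {
    abort(sprintf(
      "Model `%s` needs covariate `%s`, which is absent from the records.",
      model_id, variable
    ))
  }
  x <- records[[variable]]
  if (any(is.na(x))) {
    abort(sprintf(
      "Model `%s`: covariate `%s` is missing for %d record(s).",
      model_id, variable, sum(is.na(x))
    ))
  }
  if (numeric && !is.numeric(x)) {
    abort(sprintf(
      "Model `%s`: covariate `%s` must be numeric.", model_id, variable
    ))
  }
  x
}

#' Individual survival probability S(t | lp)
#'
#' Combines the baseline survival with a linear predictor.  Under
#' `PH_POWER` (proportional hazards) S(t) = S0(t)^exp(lp); under
#' `STATED_MULTIPLICATIVE` S(t) = min(1, S0(t) * exp(lp)), a literal
#' multiplicative reading that is clamped so the result stays a
#' probability.
#'
#' @param t Time (years), nonnegative; vectorised with `lp`.
#' @param lp Linear predictor value(s).
#' @param coefs A [coefficient_set()] with a baseline.
#' @return Survival probabilities in \[0, 1\].
#' @export
survival_probability <- function(t, lp, coefs) {
  s0 <- baseline_survival(coefs, t)
  switch(coefs$combine_mode,
    PH_POWER = s0^exp(lp),
    STATED_MULTIPLICATIVE = pmin(1, s0 * exp(lp))
  )
}

#' Icelandic-style survival risk score
#'
#' Scores each record with the approximate hazard of progression over the
#' next `delta_t` years, conditional on being disease-free at time `t`:
#' `100 * (1 - S(t + delta_t) / S(t))`, where `t` is the time since
#' diabetes diagnosis at the index screening (the `duration_years`
#' covariate) and S combines the set's baseline survival with the record's
#' linear predictor.  The factor 100 puts the score on a more stable scale
#' for ROC analysis than the raw probability.
#'
#' @param cohort Cohort records with the covariates named by `coefs` and a
#'   `duration_years` column (or pass `t` explicitly).
#' @param coefs A [coefficient_set()] with a baseline.
#' @param delta_t Risk horizon of the hazard approximation in years;
#'   default 1/12 (one month).
#' @param t Optional explicit time-since-diagnosis vector overriding
#'   `cohort$duration_years`.
#' @return A tibble: `patient_id` (if present), `model_id`, `lp`, `score`.
#'   Scores are strictly in (0, 100) whenever S is strictly decreasing.
#' @export
score_icelandic <- function(cohort, coefs, delta_t = 1 / 12, t = NULL) {
  stopifnot(inherits(coefs, "coefficient_set"), delta_t > 0)
  t <- t %||% fetch_covariate(cohort, "duration_years", coefs$model_id)
  if (any(t < 0)) abort("Time since diagnosis must be nonnegative.")
  lp <- linear_predictor(cohort, coefs)
  s_t <- survival_probability(t, lp, coefs)
  if (any(s_t <= 0)) {
    abort(sprintf(
      "Model `%s`: survival at t is zero for %d record(s); the conditional hazard is undefined.",
      coefs$model_id, sum(s_t <= 0)
    ))
  }
  s_next <- survival_probability(t + delta_t, lp, coefs)
  score_tbl(cohort, coefs$model_id, lp, score = 100 * (1 - s_next / s_t))
}

#' Gloucester-style grade/score models
#'
#' Three variants:
#' \describe{
#'   \item{`TWO_GRADES_ONLY`}{the score is the categorical coefficient for
#'     the record's two-screening risk group; at most seven distinct values
#'     (groups A, D-I) arise on any cohort.}
#'   \item{`TWO_GRADES_SYSTEMIC`}{risk-group term plus continuous terms
#'     (HbA1c and total cholesterol at minimum).}
#'   \item{`ONE_GRADE_SYSTEMIC`}{the index-screening DR category
#'     (`index_category`) plus HbA1c, total cholesterol and diabetes
#'     duration.}
#' }
#' Records in the excluded groups B/C cannot be scored and raise an error.
#'
#' @param cohort Cohort records.
#' @param coefs A [coefficient_set()] whose categorical variable matches the
#'   variant (`risk_group` for the two-grade variants, `index_category` for
#'   the one-grade variant).
#' @param variant One of `"TWO_GRADES_ONLY"`, `"TWO_GRADES_SYSTEMIC"`,
#'   `"ONE_GRADE_SYSTEMIC"`.
#' @return A tibble: `patient_id` (if present), `model_id`, `lp`, `score`.
#' @export
score_gloucester <- function(cohort, coefs,
                             variant = c(
                               "TWO_GRADES_ONLY", "TWO_GRADES_SYSTEMIC",
                               "ONE_GRADE_SYSTEMIC"
                             )) {
  variant <- arg_match(variant)
  stopifnot(inherits(coefs, "coefficient_set"))
  if (is.null(coefs$categorical)) {
    abort(sprintf(
      "Model `%s`: Gloucester variants need a categorical grade term.",
      coefs$model_id
    ))
  }
  grade_var <- switch(variant,
    TWO_GRADES_ONLY = "risk_group",
    TWO_GRADES_SYSTEMIC = "risk_group",
    ONE_GRADE_SYSTEMIC = "index_category"
  )
  if (coefs$categorical$variable != grade_var) {
    abort(sprintf(
      "Model `%s`: variant %s requires the categorical term on `%s`, not `%s`.",
      coefs$model_id, variant, grade_var, coefs$categorical$variable
    ))
  }
  if (grade_var == "risk_group") {
    rg <- as.character(fetch_covariate(cohort, "risk_group", coefs$model_id,
      numeric = FALSE
    ))
    if (any(risk_group_excluded(rg))) {
      abort(sprintf(
        "Model `%s`: %d record(s) are in excluded risk group B/C; no risk prediction is defined for them.",
        coefs$model_id, sum(risk_group_excluded(rg))
      ))
    }
  }
  if (variant == "TWO_GRADES_ONLY" && length(coefs$terms)) {
    abort(sprintf(
      "Model `%s`: TWO_GRADES_ONLY uses the risk-group term only; remove continuous terms.",
      coefs$model_id
    ))
  }
  required <- switch(variant,
    TWO_GRADES_ONLY = character(),
    TWO_GRADES_SYSTEMIC = c("hba1c_pct", "total_cholesterol"),
    ONE_GRADE_SYSTEMIC = c("hba1c_pct", "total_cholesterol", "duration_years")
  )
  for (v in required) fetch_covariate(cohort, v, coefs$model_id)
  lp <- linear_predictor(cohort, coefs)
  score_tbl(cohort, coefs$model_id, lp, score = lp)
}

score_tbl <- function(cohort, model_id, lp, score) {
  out <- tibble(model_id = model_id, lp = lp, score = score)
  if ("patient_id" %in% names(cohort)) {
    out <- bind_cols(tibble(patient_id = cohort$patient_id), out)
  }
  out
}
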