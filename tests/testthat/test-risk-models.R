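demo_set <- function(...) {
  coefficient_set("demo", ...)
}

test_that("coefficient sets are validated on construction and load", {
  expect_error(coefficient_set(""), "model_id")
  expect_error(demo_set(terms = list(list(variable = "x"))), "beta")
  expect_error(
    demo_set(terms = list(list(variable = "x", beta = 1, transform = "sqrt"))),
    "transform"
  )
  expect_error(
    demo_set(baseline = list(family = "gompertz")),
    "Unknown baseline"
  )
  expect_error(
    demo_set(baseline = list(family = "table", time = c(0, 1), surv = c(1, 1.2))),
    "nonincreasing"
  )
  expect_error(
    demo_set(baseline = list(family = "table", time = c(1, 2), surv = c(0.9, 0.8)))$baseline,
    NA
  )
  expect_error(
    demo_set(categorical = list(variable = "g", levels = list(A = "x"))),
    "finite numbers"
  )

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "model_id: roundtrip",
    "combine_mode: PH_POWER",
    "baseline: {family: exponential, rate: 0.1}",
    "terms:",
    "  - {variable: hba1c_pct, beta: 0.5}"
  ), path)
  cs <- read_coefficients(path)
  expect_s3_class(cs, "coefficient_set")
  expect_equal(cs$model_id, "roundtrip")
  expect_equal(cs$baseline$rate, 0.1)
  expect_error(read_coefficients(file.path(tempdir(), "nope.yaml")), "not found")
})

test_that("the shipped illustrative coefficient sets load and score", {
  for (which in c(
    "icelandic", "gloucester_two_grades",
    "gloucester_two_grades_systemic", "gloucester_one_grade_systemic"
  )) {
    expect_s3_class(example_coefficients(which), "coefficient_set")
  }
})

test_that("the linear predictor is the independent sum of its terms", {
  # null model
  expect_equal(linear_predictor(tibble::tibble(x = 5), demo_set()), 0)
  # one-term product
  one <- demo_set(terms = list(list(variable = "hba1c_pct", beta = 0.5)))
  expect_equal(linear_predictor(tibble::tibble(hba1c_pct = 6.8), one), 3.4)
  # multi-term configuration against a spreadsheet-style tally computed
  # independently of the engine
  cs <- demo_set(
    terms = list(
      list(variable = "hba1c_pct", beta = 0.31, center = 6.8),
      list(variable = "sbp", beta = 0.018, center = 136),
      list(variable = "total_cholesterol", beta = -0.2, transform = "log"),
      list(variable = "duration_years", beta = 0.045)
    ),
    categorical = list(variable = "risk_group", levels = list(A = 0, D = 1.1))
  )
  rec <- tibble::tibble(
    hba1c_pct = c(7.9, 6.1), sbp = c(150, 128),
    total_cholesterol = c(5.5, 4.2), duration_years = c(12, 0.5),
    risk_group = c("D", "A")
  )
  expected <- vapply(1:2, function(i) {
    0.31 * (rec$hba1c_pct[i] - 6.8) + 0.018 * (rec$sbp[i] - 136) +
      -0.2 * log(rec$total_cholesterol[i]) + 0.045 * rec$duration_years[i] +
      c(D = 1.1, A = 0)[[rec$risk_group[i]]]
  }, numeric(1))
  expect_equal(linear_predictor(rec, cs), expected)
})

test_that("missing covariates are reported by name", {
  cs <- demo_set(terms = list(list(variable = "sbp", beta = 1)))
  expect_error(linear_predictor(tibble::tibble(hba1c_pct = 7), cs), "sbp")
  expect_error(linear_predictor(tibble::tibble(sbp = NA_real_), cs), "missing")
})

test_that("survival probabilities follow the configured combination mode", {
  expo <- demo_set(baseline = list(family = "exponential", rate = 0.1))
  # null linear predictor reproduces the baseline exactly
  t <- c(0, 0.5, 1, 5)
  expect_equal(survival_probability(t, 0, expo), exp(-0.1 * t))
  # proportional hazards closed form: S0(t)^exp(lp) = exp(-lambda t e^lp)
  expect_equal(
    survival_probability(1, log(2), expo),
    exp(-0.2)
  )
  # t = 0 gives 1 whenever the combination cannot raise survival above S0
  mult <- demo_set(
    baseline = list(family = "exponential", rate = 0.1),
    combine_mode = "STATED_MULTIPLICATIVE"
  )
  expect_equal(survival_probability(0, 0.7, expo), 1)
  expect_equal(survival_probability(0, 0.7, mult), 1)
  # the literal multiplicative form is clamped to a probability
  expect_equal(survival_probability(1, 5, mult), 1)
  expect_equal(survival_probability(1, -1, mult), exp(-0.1) * exp(-1))
  expect_error(survival_probability(-1, 0, expo), "t >= 0")
})

test_that("weibull and tabulated baselines behave and refuse extrapolation", {
  wb <- demo_set(baseline = list(family = "weibull", shape = 1.3, scale = 20))
  expect_equal(baseline_survival(wb, c(0, 20)), c(1, exp(-1)))
  tab <- demo_set(baseline = list(
    family = "table", time = c(1, 2, 4), surv = c(0.9, 0.8, 0.5)
  ))
  expect_equal(baseline_survival(tab, 0), 1)
  expect_equal(baseline_survival(tab, 2), 0.8)
  expect_equal(baseline_survival(tab, 3), 0.65) # linear interpolation
  expect_error(baseline_survival(tab, 5), "extrapolate")
})

test_that("the survival risk score matches the closed-form hazard", {
  # exponential baseline, lp = 0: 100 * (1 - exp(-lambda * dt))
  lambda <- 0.12
  cs <- demo_set(baseline = list(family = "exponential", rate = lambda))
  rec <- tibble::tibble(duration_years = 7)
  got <- score_icelandic(rec, cs)$score
  expect_equal(got, 100 * (1 - exp(-lambda / 12)), tolerance = 1e-12)
  # no hazard: constant survival gives score 0
  flat <- demo_set(baseline = list(family = "exponential", rate = 0))
  expect_equal(score_icelandic(rec, flat)$score, 0)
  # a custom horizon is respected
  got6 <- score_icelandic(rec, cs, delta_t = 0.5)$score
  expect_equal(got6, 100 * (1 - exp(-lambda * 0.5)), tolerance = 1e-12)
})

test_that("survival scores rank records exactly as their linear predictors", {
  cs <- demo_set(
    terms = list(list(variable = "hba1c_pct", beta = 0.4, center = 6.8)),
    baseline = list(family = "weibull", shape = 1.2, scale = 30)
  )
  withr::with_seed(11, {
    rec <- tibble::tibble(
      hba1c_pct = rnorm(1000, 6.8, 1.2),
      duration_years = runif(1000, 0, 30)
    )
  })
  scored <- score_icelandic(rec, cs)
  # within fixed t the score is strictly monotone in lp; compare at a
  # common time origin
  same_t <- score_icelandic(rec, cs, t = rep(5, 1000))
  expect_equal(order(same_t$score), order(same_t$lp))
  expect_true(all(scored$score > 0 & scored$score < 100))
  # purity: identical inputs give identical outputs
  expect_identical(scored, score_icelandic(rec, cs))
})

test_that("grade-only scores are determined by the risk group alone", {
  cs <- example_coefficients("gloucester_two_grades")
  rec <- tibble::tibble(risk_group = c("A", "D", "A", "I"))
  got <- score_gloucester(rec, cs, "TWO_GRADES_ONLY")$score
  expect_equal(got[1], got[3])
  expect_equal(got, unlist(cs$categorical$levels)[rec$risk_group], ignore_attr = TRUE)
  # at most 7 distinct values over any cohort
  all_groups <- tibble::tibble(risk_group = rep(c("A", "D", "E", "F", "G", "H", "I"), 3))
  expect_lte(length(unique(score_gloucester(all_groups, cs, "TWO_GRADES_ONLY")$score)), 7)
})

test_that("records in excluded groups B/C cannot be scored", {
  cs <- example_coefficients("gloucester_two_grades")
  expect_error(
    score_gloucester(tibble::tibble(risk_group = "B"), cs, "TWO_GRADES_ONLY"),
    "excluded risk group"
  )
})

test_that("a zero systemic coefficient reduces to the grade-only structure", {
  base_levels <- list(A = 0, D = 2, E = 1.3, F = 0.9, G = 1.6, H = 1.1, I = 2.1)
  with_zero <- demo_set(
    categorical = list(variable = "risk_group", levels = base_levels),
    terms = list(
      list(variable = "hba1c_pct", beta = 0.3, center = 6.8),
      list(variable = "total_cholesterol", beta = 0, center = 5)
    )
  )
  without <- demo_set(
    categorical = list(variable = "risk_group", levels = base_levels),
    terms = list(list(variable = "hba1c_pct", beta = 0.3, center = 6.8))
  )
  rec <- tibble::tibble(
    risk_group = c("A", "D"), hba1c_pct = c(7.5, 6.2),
    total_cholesterol = c(9, 3)
  )
  expect_equal(
    score_gloucester(rec, with_zero, "TWO_GRADES_SYSTEMIC")$score,
    score_gloucester(rec, without, "TWO_GRADES_SYSTEMIC")$score
  )
})

test_that("the one-grade variant sums grade category and systemic terms", {
  cs <- example_coefficients("gloucester_one_grade_systemic")
  rec <- tibble::tibble(
    index_category = "MILD_ONE_EYE", hba1c_pct = 8.0,
    total_cholesterol = 6.0, duration_years = 10
  )
  expected <- 1.4 + 0.35 * (8.0 - 6.8) + 0.15 * (6.0 - 5.0) + 0.03 * 10
  expect_equal(score_gloucester(rec, cs, "ONE_GRADE_SYSTEMIC")$score, expected)
})

test_that("variant requirements are enforced", {
  cs <- example_coefficients("gloucester_two_grades")
  expect_error(
    score_gloucester(tibble::tibble(risk_group = "A"), cs, "TWO_GRADES_SYSTEMIC"),
    "hba1c_pct"
  )
  one <- example_coefficients("gloucester_one_grade_systemic")
  expect_error(
    score_gloucester(tibble::tibble(risk_group = "A"), one, "TWO_GRADES_ONLY"),
    "categorical term"
  )
})
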