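test_that("full-period AUC matches the exhaustive pairwise oracle", {
  # trivia: perfect separation and complete ties
  d1 <- tibble::tibble(score = c(2, 1), followup_years = c(1, 3), event = c(1L, 0L))
  expect_equal(roc_auc_full(d1, n_boot = 0)$auc, 1.0)
  d2 <- tibble::tibble(score = rep(1, 6), followup_years = rep(2, 6), event = rep(0:1, 3))
  expect_equal(roc_auc_full(d2, n_boot = 0)$auc, 0.5)
  # 50 random samples, ties included, against the brute-force count
  withr::with_seed(7, {
    d <- tibble::tibble(
      score = sample(seq(0, 2, by = 0.25), 50, replace = TRUE),
      followup_years = runif(50, 0.5, 5),
      event = rbinom(50, 1, 0.4)
    )
  })
  got <- roc_auc_full(d, n_boot = 0)$auc
  oracle <- brute_force_auc(d$score[d$event == 1], d$score[d$event == 0])
  expect_equal(got, oracle, tolerance = 1e-14)
  expect_error(roc_auc_full(dplyr::filter(d, event == 1), n_boot = 0), "single outcome")
})

test_that("full-period AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    d <- tibble::tibble(
      score = rnorm(120),
      followup_years = runif(120, 0.5, 4),
      event = rbinom(120, 1, 0.3)
    )
  })
  got <- roc_auc_full(d, n_boot = 0)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(d$event, d$score,
    direction = "<", quiet = TRUE
  )))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("time-dependent AUC reduces to Mann-Whitney without early censoring", {
  withr::with_seed(31, {
    for (i in 1:25) {
      d <- samples_no_early_censoring(n = sample(10:60, 1), horizon = 2)
      if (sum(d$event) == 0 || all(d$followup_years <= 2)) next
      got <- tdroc_auc(d, horizon = 2, n_boot = 0)$auc
      oracle <- brute_force_auc(
        d$score[d$event == 1 & d$followup_years <= 2],
        d$score[d$followup_years > 2]
      )
      expect_equal(got, oracle, tolerance = 1e-12)
    }
  })
})

test_that("time-dependent AUC handles separation, errors and weights", {
  # perfectly separating score
  d <- tibble::tibble(
    score = c(5, 6, 1, 2, 3),
    followup_years = c(0.5, 1.5, 3, 3, 4),
    event = c(1L, 1L, 0L, 0L, 0L)
  )
  expect_equal(tdroc_auc(d, horizon = 2, n_boot = 0)$auc, 1.0)
  # no cases or no controls by the horizon is undefined
  expect_error(tdroc_auc(d, horizon = 0.2, n_boot = 0), "undefined")
  expect_error(tdroc_auc(d, horizon = 10, n_boot = 0), "undefined")
  # censoring before the horizon reweights but keeps the AUC a probability
  withr::with_seed(41, {
    dc <- tibble::tibble(
      score = rnorm(300),
      t_ev = rexp(300, 0.3),
      t_cens = rexp(300, 0.2)
    ) |>
      dplyr::mutate(
        followup_years = pmin(t_ev, t_cens),
        event = as.integer(t_ev <= t_cens)
      )
  })
  a <- tdroc_auc(dc, horizon = 2, n_boot = 0)
  expect_gte(a$auc, 0)
  expect_lte(a$auc, 1)
  expect_equal(a$roc$fpr[1], 0)
  expect_equal(dplyr::last(a$roc$tpr), 1)
  expect_true(all(diff(a$roc$fpr) >= 0) && all(diff(a$roc$tpr) >= 0))
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(51, {
    d <- tibble::tibble(
      score = rnorm(150),
      t_ev = rexp(150, 0.4),
      t_cens = runif(150, 0.5, 6)
    ) |>
      dplyr::mutate(
        followup_years = pmin(t_ev, t_cens),
        event = as.integer(t_ev <= t_cens)
      )
  })
  base_td <- tdroc_auc(d, horizon = 2, n_boot = 0)$auc
  base_full <- roc_auc_full(d, n_boot = 0)$auc
  for (f in list(function(x) 3 * x - 2, function(x) exp(x), function(x) atan(x))) {
    dd <- dplyr::mutate(d, score = f(score))
    expect_equal(tdroc_auc(dd, horizon = 2, n_boot = 0)$auc, base_td)
    expect_equal(roc_auc_full(dd, n_boot = 0)$auc, base_full)
  }
})

test_that("percentile bootstrap intervals are seeded and degenerate-safe", {
  d <- tibble::tibble(x = rnorm(40))
  ci1 <- bootstrap_ci(d, function(dd) mean(dd$x), n_boot = 50, seed = 9)
  ci2 <- bootstrap_ci(d, function(dd) mean(dd$x), n_boot = 50, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lower"]], ci1[["upper"]])
  # constant statistic collapses to a point
  cc <- bootstrap_ci(d, function(dd) 0.42, n_boot = 20, seed = 1)
  expect_equal(unname(cc), c(0.42, 0.42))
  expect_error(bootstrap_ci(d, mean, n_boot = 1, seed = 1), "at least 2")
  expect_error(bootstrap_ci(d, function(dd) mean(dd$x), n_boot = 10), "seed")
  # unstable statistic is reported, not silently summarised
  expect_error(
    bootstrap_ci(d, function(dd) stop("boom"), n_boot = 10, seed = 2),
    "unstable"
  )
})

test_that("AUC objects carry CI, tidy/glance methods and plots", {
  withr::with_seed(61, {
    d <- samples_no_early_censoring(120)
  })
  a <- tdroc_auc(d, horizon = 2, n_boot = 40, seed = 3)
  expect_s3_class(a, "rdr_auc")
  expect_lte(a$ci_lower, a$auc)
  expect_gte(a$ci_upper, a$auc)
  g <- glance(a)
  expect_equal(nrow(g), 1)
  expect_named(g, c(
    "model_id", "method", "horizon", "auc", "ci_lower", "ci_upper",
    "n", "n_cases", "n_controls", "n_bootstrap"
  ))
  roc <- tidy(a)
  expect_equal(roc[1, c("fpr", "tpr")], tibble::tibble(fpr = 0, tpr = 0))
  p <- autoplot(a)
  expect_s3_class(p, "ggplot")
})

test_that("incidence rates are per 1000 person-years, rounded half-up", {
  expect_equal(rate_per_1000py(3, 537), 5.6)
  expect_equal(rate_per_1000py(0, 11), 0.0)
  expect_equal(rate_per_1000py(20, 2585), 7.7)
  # half-up at the first decimal, not banker's rounding
  expect_equal(rate_per_1000py(25, 1000), 25.0)
  expect_equal(rate_per_1000py(1, 40), 25.0)
  expect_equal(rate_per_1000py(3, 80), 37.5)
  expect_equal(rate_per_1000py(9, 2400), 3.8) # 3.75 rounds up
  expect_error(rate_per_1000py(3, 0), "positive")
  expect_error(rate_per_1000py(-1, 10), "nonnegative")
})

test_that("quintile strata are near-equal with larger strata first", {
  make_cohort <- function(n) {
    tibble::tibble(
      patient_id = sprintf("p%04d", seq_len(n)),
      score = seq_len(n) / n,
      followup_years = rep(2, n),
      event = rep(0L, n)
    )
  }
  q939 <- quintile_table(make_cohort(939))
  expect_equal(q939$n, c(188, 188, 188, 188, 187))
  q10 <- quintile_table(make_cohort(10))
  expect_equal(q10$n, rep(2, 5))
  # events in the top-scoring records land in stratum 5
  d <- make_cohort(10) |> dplyr::mutate(event = as.integer(score > 0.8))
  expect_equal(quintile_table(d)$events, c(0, 0, 0, 0, 2))
})

test_that("ties across quintile boundaries break deterministically by patient id", {
  d <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:10),
    score = rep(1, 10),
    followup_years = 1:10 / 2,
    event = rep(0L, 10)
  )
  q1 <- quintile_table(d)
  q2 <- quintile_table(d[sample(10), ])
  expect_equal(q1, q2)
  # with all scores tied, ordering is by patient id, so person-years per
  # stratum are determined
  expect_equal(q1$person_years, c(1.5, 3.5, 5.5, 7.5, 9.5))
})

test_that("rate tables conserve cohort totals", {
  withr::with_seed(71, {
    d <- tibble::tibble(
      patient_id = sprintf("p%03d", 1:500),
      score = rnorm(500),
      followup_years = runif(500, 0.5, 6),
      event = rbinom(500, 1, 0.05),
      risk_group = sample(c("A", "D", "E", "G"), 500,
        replace = TRUE, prob = c(0.85, 0.07, 0.05, 0.03)
      )
    )
  })
  q <- quintile_table(d)
  expect_equal(sum(q$n), 500)
  expect_equal(sum(q$events), sum(d$event))
  expect_equal(sum(q$person_years), sum(d$followup_years))
  g <- group_table(d)
  expect_setequal(g$stratum, c("A", "D", "E", "G"))
  expect_equal(sum(g$n), 500)
  expect_equal(sum(g$person_years), sum(d$followup_years))
  # a stratum with no events reports rate 0.0
  none <- dplyr::mutate(d, event = 0L)
  expect_equal(unique(group_table(none)$rate_per_1000py), 0.0)
})

test_that("hand-built group tables match their construction", {
  d <- tibble::tibble(
    risk_group = c("A", "A", "A", "D", "D", "I"),
    followup_years = c(2, 3, 5, 1, 1, 0.5),
    event = c(0L, 1L, 0L, 1L, 0L, 0L)
  )
  g <- group_table(d)
  expect_equal(nrow(g), 3)
  a_row <- g[g$stratum == "A", ]
  expect_equal(a_row$n, 3)
  expect_equal(a_row$events, 1)
  expect_equal(a_row$person_years, 10)
  expect_equal(a_row$rate_per_1000py, 100.0)
})
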