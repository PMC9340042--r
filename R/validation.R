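# Discrimination and incidence-rate validation.
#
# Time-dependent ROC uses the cumulative/dynamic definition at a horizon
# tau: cases are subjects with an observed event by tau, controls are
# subjects still event-free (and under observation) at tau.  Censoring
# before tau is handled by inverse-probability-of-censoring weights (IPCW)
# from a reverse Kaplan-Meier estimate of the censoring distribution; with
# no censoring before the horizon the estimator reduces exactly to the
# Mann-Whitney statistic over cases vs controls.

#' Time-dependent ROC AUC (cumulative/dynamic, IPCW)
#'
#' Estimates discrimination of a risk score for events occurring within
#' `horizon` years.  Cases are observed events with `time <= horizon`;
#' controls are subjects with `time > horizon`.  Cases are weighted by
#' `1 / G(T_i)` and controls by `1 / G(horizon)`, where `G` is the
#' Kaplan-Meier estimate of the censoring survival function; tied scores
#' contribute one half.
#'
#' @param data Data frame with one row per subject.
#' @param score,time,event Column names (strings) of the risk score, the
#'   follow-up time in years, and the 0/1 event indicator.  Defaults
#'   `"score"`, `"followup_years"`, `"event"` match [build_cohort()] output
#'   joined to a score table.
#' @param horizon Prediction horizon in years (default 2).
#' @param n_boot Number of bootstrap resamples for the percentile 95% CI
#'   (default 100); 0 skips the CI.
#' @param seed Seed for the bootstrap; required when `n_boot > 0`.
#' @param conf_level Confidence level of the percentile interval.
#' @return An object of class `rdr_auc`: a list with `model_id`, `method`,
#'   `horizon`, `auc`, `ci_lower`/`ci_upper`, `n`, `n_cases`, `n_controls`,
#'   `n_bootstrap` and a `roc` tibble of (fpr, tpr) points from (0,0) to
#'   (1,1).  Supports [tidy()], [glance()] and [autoplot()].
#' @export
tdroc_auc <- function(data, score = "score", time = "followup_years",
                      event = "event", horizon = 2, n_boot = 100,
                      seed = NULL, conf_level = 0.95) {
  d <- extract_samples(data, score, time, event)
  est <- tdroc_estimate(d, horizon)
  boot <- boot_auc_ci(d, function(dd) tdroc_estimate(dd, horizon)$auc,
    n_boot = n_boot, seed = seed, conf_level = conf_level
  )
  new_rdr_auc(
    model_id = attr(data, "model_id") %||% NA_character_,
    method = "tdroc_ipcw", horizon = horizon, est = est, boot = boot
  )
}

#' Standard (full-period) ROC AUC
#'
#' Mann-Whitney AUC treating the event indicator over the whole follow-up
#' as the binary label, ignoring censoring times.  Tied scores contribute
#' one half.
#'
#' @inheritParams tdroc_auc
#' @return An `rdr_auc` object with `horizon = Inf` (`FULL_PERIOD`).
#' @export
roc_auc_full <- function(data, score = "score", time = "followup_years",
                         event = "event", n_boot = 100, seed = NULL,
                         conf_level = 0.95) {
  d <- extract_samples(data, score, time, event, need_time = FALSE)
  est <- binary_roc_estimate(d$score[d$event == 1], d$score[d$event == 0])
  est$n <- nrow(d)
  boot <- boot_auc_ci(
    d,
    function(dd) {
      binary_roc_estimate(dd$score[dd$event == 1], dd$score[dd$event == 0])$auc
    },
    n_boot = n_boot, seed = seed, conf_level = conf_level
  )
  new_rdr_auc(
    model_id = attr(data, "model_id") %||% NA_character_,
    method = "roc_full_period", horizon = Inf, est = est, boot = boot
  )
}

extract_samples <- function(data, score, time, event, need_time = TRUE,
                            call = rlang::caller_env()) {
  need <- c(score, if (need_time) time, event)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf(
      "Data is missing column(s): %s.", paste(missing_cols, collapse = ", ")
    ), call = call)
  }
  d <- tibble(
    score = as.numeric(data[[score]]),
    time = if (need_time && time %in% names(data)) as.numeric(data[[time]]) else NA_real_,
    event = as.integer(data[[event]])
  )
  if (any(is.na(d$score))) abort("Scores contain missing values.", call = call)
  if (!all(d$event %in% 0:1)) abort("`event` must be 0/1.", call = call)
  if (need_time) {
    if (any(is.na(d$time))) abort("Follow-up times contain missing values.", call = call)
    if (any(d$time <= 0)) abort("Follow-up times must be positive.", call = call)
  }
  d
}

# Core cumulative/dynamic IPCW estimator on a tibble(score, time, event).
tdroc_estimate <- function(d, horizon) {
  is_case <- d$event == 1 & d$time <= horizon
  is_control <- d$time > horizon
  if (!any(is_case) || !any(is_control)) {
    abort(sprintf(
      "AUC at horizon %g is undefined: %d case(s) and %d control(s).",
      horizon, sum(is_case), sum(is_control)
    ))
  }
  g <- censoring_survfun(d$time, d$event)
  w_case <- 1 / g(d$time[is_case])
  w_control <- rep(1 / g(horizon), sum(is_control))
  if (any(!is.finite(w_case)) || any(!is.finite(w_control))) {
    abort("Censoring weights are unstable (G-hat reaches 0 before the horizon).")
  }
  weighted_roc(d$score[is_case], w_case, d$score[is_control], w_control)
}

# Reverse Kaplan-Meier: survival function of the censoring distribution,
# treating events as censorings and vice versa.  Returns a step function.
censoring_survfun <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  stepfun(fit$time, c(1, fit$surv), right = FALSE)
}

binary_roc_estimate <- function(case_scores, control_scores) {
  if (!length(case_scores) || !length(control_scores)) {
    abort("AUC is undefined with a single outcome class.")
  }
  weighted_roc(
    case_scores, rep(1, length(case_scores)),
    control_scores, rep(1, length(control_scores))
  )
}

# Weighted Mann-Whitney AUC plus ROC curve.  Ties contribute one half.
weighted_roc <- function(case_scores, case_w, control_scores, control_w) {
  thresholds <- sort(unique(c(case_scores, control_scores)), decreasing = TRUE)
  wins <- vapply(seq_along(case_scores), function(i) {
    sum(control_w * ((case_scores[i] > control_scores) +
      0.5 * (case_scores[i] == control_scores)))
  }, numeric(1))
  auc <- sum(case_w * wins) / (sum(case_w) * sum(control_w))
  tpr <- vapply(thresholds, function(th) {
    sum(case_w[case_scores >= th])
  }, numeric(1)) / sum(case_w)
  fpr <- vapply(thresholds, function(th) {
    sum(control_w[control_scores >= th])
  }, numeric(1)) / sum(control_w)
  roc <- tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, fpr), tpr = c(0, tpr)
  ) |>
    add_row(threshold = -Inf, fpr = 1, tpr = 1)
  list(
    auc = auc, roc = roc, n = length(case_scores) + length(control_scores),
    n_cases = length(case_scores), n_controls = length(control_scores)
  )
}

boot_auc_ci <- function(d, statistic, n_boot, seed, conf_level) {
  if (n_boot == 0) {
    return(list(lower = NA_real_, upper = NA_real_, n_boot = 0L))
  }
  ci <- bootstrap_ci(d, statistic,
    n_boot = n_boot, seed = seed,
    conf_level = conf_level
  )
  list(lower = ci[["lower"]], upper = ci[["upper"]], n_boot = as.integer(n_boot))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (patients) with replacement, recomputes `statistic` on
#' each resample, and returns the percentile interval.  Resamples on which
#' the statistic is undefined (it errors or returns `NA`) are dropped; if
#' more than half are undefined the interval is declared unstable.
#'
#' @param data Data frame resampled at the row (patient) level.
#' @param statistic Function taking a resampled data frame and returning a
#'   single number.
#' @param n_boot Number of resamples (default 100).
#' @param seed Integer seed; required, so intervals are reproducible.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' d <- tibble::tibble(x = rnorm(50))
#' bootstrap_ci(d, function(dd) mean(dd$x), n_boot = 200, seed = 1)
bootstrap_ci <- function(data, statistic, n_boot = 100, seed = NULL,
                         conf_level = 0.95) {
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  if (is.null(seed)) abort("A `seed` is required for a reproducible bootstrap.")
  n <- nrow(data)
  stats <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(statistic(data[idx, , drop = FALSE])),
        error = function(e) NA_real_
      )
    }, numeric(1))
  })
  if (mean(is.na(stats)) > 0.5) {
    abort(sprintf(
      "Bootstrap unstable: the statistic was undefined on %d of %d resamples.",
      sum(is.na(stats)), n_boot
    ))
  }
  alpha <- (1 - conf_level) / 2
  q <- quantile(stats, probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  c(lower = q[1], upper = q[2])
}

# Rate tables -----------------------------------------------------------------

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Incidence rate per 1000 person-years
#'
#' @param events Event count(s).
#' @param person_years Exposure in person-years (positive).
#' @return `1000 * events / person_years`, rounded half-up to one decimal.
#' @export
#' @examples
#' rate_per_1000py(3, 537) # 5.6
#' rate_per_1000py(20, 2585) # 7.7
rate_per_1000py <- function(events, person_years) {
  if (any(person_years <= 0)) abort("`person_years` must be positive.")
  if (any(events < 0)) abort("`events` must be nonnegative.")
  round_half_up(1000 * events / person_years, 1)
}

#' Risk-score quintile rate table
#'
#' Ranks a scored cohort by risk score (ascending; quintile 1 is lowest
#' risk), splits it into five near-equal strata — sizes differ by at most
#' one, with the larger strata first — and reports events, person-years and
#' the referral rate per 1000 person-years per stratum.  Ties spanning a
#' boundary are broken deterministically by patient id.
#'
#' @param data Cohort records joined with a score column: needs `score`,
#'   `followup_years`, `event` and (for deterministic tie-breaks)
#'   `patient_id`.
#' @return A tibble of class `rdr_rate_table`: `stratum`, `n`, `events`,
#'   `person_years`, `rate_per_1000py`.
#' @export
quintile_table <- function(data) {
  need <- c("score", "followup_years", "event")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf(
      "Data is missing column(s): %s.", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(data) < 5) abort("Need at least 5 records to form quintiles.")
  ord <- if ("patient_id" %in% names(data)) {
    order(data$score, data$patient_id)
  } else {
    order(data$score)
  }
  n <- nrow(data)
  base <- n %/% 5
  sizes <- base + (seq_len(5) <= n %% 5)
  stratum <- rep(seq_len(5), times = sizes)
  d <- data[ord, , drop = FALSE] |>
    mutate(stratum = as.character(stratum))
  rate_table(d, "stratum")
}

#' Risk-group rate table
#'
#' One row per observed risk group (A, D-I) with patient counts, events,
#' person-years and referral rate per 1000 person-years — the stratified
#' report of the screening-only grade model.
#'
#' @param cohort Cohort records with `risk_group`, `followup_years`, `event`.
#' @return A tibble of class `rdr_rate_table`.
#' @export
group_table <- function(cohort) {
  need <- c("risk_group", "followup_years", "event")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(sprintf(
      "Cohort is missing column(s): %s.", paste(missing_cols, collapse = ", ")
    ))
  }
  d <- as_tibble(cohort) |> mutate(stratum = as.character(.data$risk_group))
  rate_table(d, "stratum")
}

rate_table <- function(d, stratum_col) {
  out <- d |>
    group_by(stratum = .data[[stratum_col]]) |>
    summarise(
      n = n(),
      events = sum(.data$event),
      person_years = sum(.data$followup_years),
      .groups = "drop"
    ) |>
    mutate(rate_per_1000py = rate_per_1000py(.data$events, .data$person_years)) |>
    arrange(.data$stratum)
  class(out) <- c("rdr_rate_table", class(out))
  out
}

# rdr_auc class ---------------------------------------------------------------

new_rdr_auc <- function(model_id, method, horizon, est, boot) {
  structure(
    list(
      model_id = model_id, method = method, horizon = horizon,
      auc = est$auc, ci_lower = boot$lower, ci_upper = boot$upper,
      n = est$n, n_cases = est$n_cases, n_controls = est$n_controls,
      n_bootstrap = boot$n_boot, roc = est$roc
    ),
    class = "rdr_auc"
  )
}

#' @export
print.rdr_auc <- function(x, ...) {
  hz <- if (is.infinite(x$horizon)) "full follow-up period" else {
    sprintf("%g-year horizon", x$horizon)
  }
  cat(sprintf(
    "<rdr_auc> %s, %s\n  AUC %.2f", x$method, hz, x$auc
  ))
  if (!is.na(x$ci_lower)) {
    cat(sprintf(
      " (95%% CI %.2f to %.2f, %d bootstrap samples)",
      x$ci_lower, x$ci_upper, x$n_bootstrap
    ))
  }
  cat(sprintf(
    "\n  %d subjects: %d cases, %d controls\n", x$n, x$n_cases, x$n_controls
  ))
  invisible(x)
}

#' Tidy an AUC result into its ROC points
#'
#' @param x An `rdr_auc` object.
#' @param ... Unused.
#' @return A tibble of ROC points: `threshold`, `fpr`, `tpr`.
#' @export
tidy.rdr_auc <- function(x, ...) x$roc

#' One-row summary of an AUC result
#'
#' @param x An `rdr_auc` object.
#' @param ... Unused.
#' @return One-row tibble: model, method, horizon, AUC, CI bounds, counts.
#' @export
glance.rdr_auc <- function(x, ...) {
  tibble(
    model_id = x$model_id, method = x$method, horizon = x$horizon,
    auc = x$auc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    n = x$n, n_cases = x$n_cases, n_controls = x$n_controls,
    n_bootstrap = x$n_bootstrap
  )
}

#' Plot an ROC curve
#'
#' @param object An `rdr_auc` object.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
autoplot.rdr_auc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.2f", object$auc),
      subtitle = if (is.infinite(object$horizon)) {
        "Full follow-up period"
      } else {
        sprintf("%g-year horizon", object$horizon)
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot a stratified rate table
#'
#' @param object An `rdr_rate_table`.
#' @param ... Unused.
#' @return A ggplot bar chart of referral rates per 1000 person-years.
#' @export
autoplot.rdr_rate_table <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$stratum, y = .data$rate_per_1000py)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Risk stratum", y = "Referrals per 1000 person-years"
    ) +
    ggplot2::theme_minimal()
}
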