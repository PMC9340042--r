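# End-to-end orchestration and file IO.
#
# Datasets travel as three CSV tables (patients, screenings, visits) plus
# optional ground truth; a validation run writes a machine-readable JSON
# report and aligned plain-text rate tables.  Every artefact carries the
# seed and a configuration hash so reruns are reproducible bit for bit.

#' Write a simulated dataset to a directory
#'
#' Writes `patients.csv`, `screenings.csv`, `visits.csv`,
#' `ground_truth.csv` and a `manifest.json` recording the generator
#' configuration, seed and a content hash.
#'
#' @param sim An `rdr_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "rdr_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$patients, file.path(dir, "patients.csv"))
  readr::write_csv(sim$screenings, file.path(dir, "screenings.csv"))
  readr::write_csv(sim$visits, file.path(dir, "visits.csv"))
  readr::write_csv(sim$truth, file.path(dir, "ground_truth.csv"))
  cfg <- sim$config
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    tables = list(
      patients = nrow(sim$patients), screenings = nrow(sim$screenings),
      visits = nrow(sim$visits)
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing the CSV tables.
#' @return A list with tibbles `patients`, `screenings`, `visits`, and
#'   `truth` when present.
#' @export
read_dataset <- function(dir) {
  read_one <- function(name, col_types) {
    path <- file.path(dir, name)
    if (!file.exists(path)) abort(sprintf("Missing table: %s", path))
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  }
  patients <- read_one("patients.csv", readr::cols(
    patient_id = "c", sex = "c", birth_year = "i", diabetes_type = "c",
    diagnosis_date = readr::col_date()
  ))
  screenings <- read_one("screenings.csv", readr::cols(
    patient_id = "c", date = readr::col_date(),
    r_right = "i", m_right = "i", r_left = "i", m_left = "i"
  ))
  visits <- read_one("visits.csv", readr::cols(
    patient_id = "c", date = readr::col_date(), .default = "d"
  ))
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path,
      col_types = readr::cols(
        patient_id = "c", entry_date = readr::col_date(), .default = "d"
      ), progress = FALSE
    )
  }
  list(patients = patients, screenings = screenings, visits = visits, truth = truth)
}

#' Write a built cohort with its exclusion-tally sidecar
#'
#' Writes the cohort as CSV plus a JSON sidecar recording the per-reason
#' exclusion tally and the per-patient exclusion log, so the cohort-flow
#' accounting stays auditable alongside the data.
#'
#' @param cohort An `rdr_cohort` from [build_cohort()].
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>_exclusions.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "rdr_cohort"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(cohort), path)
  tally <- exclusion_tally(cohort)
  sidecar <- list(
    included = nrow(cohort),
    excluded = setNames(as.list(tally$n), tally$reason),
    excluded_patients = as.data.frame(exclusion_tally(cohort, patients = TRUE))
  )
  jsonlite::write_json(sidecar, paste0(path, "_exclusions.json"),
    auto_unbox = TRUE, pretty = TRUE, dataframe = "rows"
  )
  invisible(path)
}

#' Run the full validation pipeline
#'
#' Builds the analysis cohort, scores every configured model, and computes
#' discrimination (time-dependent AUC at the horizon and standard AUC over
#' the full follow-up period, each with a percentile bootstrap CI) plus
#' risk-stratified referral-rate tables: score quintiles for continuous
#' models and the risk-group table for the screening-only grade model.
#'
#' @param patients,screenings,visits Input tables as in [build_cohort()].
#' @param models Named list describing the models to score.  Each element
#'   is a list with `coefs` (a [coefficient_set()] or path readable by
#'   [read_coefficients()]) and `engine` (`"icelandic"` or a
#'   [score_gloucester()] variant).
#' @param horizon Prediction horizon in years (default 2).
#' @param n_boot Bootstrap resamples for AUC CIs (default 100).
#' @param seed Integer seed for the bootstrap (required).
#' @param window_days Systemic linkage window (default 180 days).
#' @return An object of class `rdr_validation`: cohort summary, exclusion
#'   tally, per-model AUC results and rate tables, scores, and the run
#'   settings.  Supports [tidy()] (AUC table), [glance()] (cohort summary)
#'   and [autoplot()] (ROC curves).
#' @export
run_validation <- function(patients, screenings, visits, models,
                           horizon = 2, n_boot = 100, seed = 1,
                           window_days = 180) {
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    abort("`models` must be a fully named list.")
  }
  cohort <- build_cohort(patients, screenings, visits,
    window_days = window_days
  )
  if (nrow(cohort) == 0) abort("No patients passed cohort construction.")

  results <- purrr::imap(models, function(m, name) {
    coefs <- m$coefs
    if (is.character(coefs)) coefs <- read_coefficients(coefs)
    engine <- m$engine %||% abort(sprintf("Model `%s` needs an `engine`.", name))
    scores <- switch(engine,
      icelandic = score_icelandic(cohort, coefs),
      TWO_GRADES_ONLY = ,
      TWO_GRADES_SYSTEMIC = ,
      ONE_GRADE_SYSTEMIC = score_gloucester(cohort, coefs, variant = engine),
      abort(sprintf("Model `%s`: unknown engine `%s`.", name, engine))
    )
    scored <- as_tibble(cohort) |>
      inner_join(scores |> select("patient_id", "score"), by = "patient_id")
    attr(scored, "model_id") <- coefs$model_id
    auc_td <- tdroc_auc(scored,
      horizon = horizon, n_boot = n_boot,
      seed = seed
    )
    auc_full <- roc_auc_full(scored, n_boot = n_boot, seed = seed + 1L)
    strata <- if (engine == "TWO_GRADES_ONLY") {
      group_table(scored)
    } else {
      quintile_table(scored)
    }
    list(
      name = name, engine = engine, model_id = coefs$model_id,
      scores = scores, auc_tdroc = auc_td, auc_full = auc_full,
      rate_table = strata
    )
  })

  settings <- list(
    horizon = horizon, n_boot = n_boot, seed = seed,
    window_days = window_days
  )
  structure(
    list(
      cohort = cohort,
      summary = followup_summary(cohort),
      exclusions = exclusion_tally(cohort),
      models = results,
      settings = settings,
      hash = rlang::hash(list(settings, purrr::map(results, "model_id")))
    ),
    class = "rdr_validation"
  )
}

#' @export
print.rdr_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<rdr_validation> %d patients, %.0f person-years, %d events (median follow-up %.1f y)\n",
    s$n, s$person_years, s$events, s$median_followup
  ))
  cat("Exclusions:", paste(
    sprintf("%s=%d", x$exclusions$reason, x$exclusions$n),
    collapse = ", "
  ), "\n\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a validation run into its AUC table
#'
#' @param x An `rdr_validation`.
#' @param ... Unused.
#' @return A tibble with one row per model and ROC method.
#' @export
tidy.rdr_validation <- function(x, ...) {
  purrr::map(x$models, function(m) {
    bind_rows(glance(m$auc_tdroc), glance(m$auc_full)) |>
      mutate(model = m$name, model_id = m$model_id, engine = m$engine) |>
      select("model", "model_id", "engine", everything())
  }) |>
    bind_rows()
}

#' One-row cohort summary of a validation run
#'
#' @param x An `rdr_validation`.
#' @param ... Unused.
#' @return One-row tibble with cohort and settings summaries.
#' @export
glance.rdr_validation <- function(x, ...) {
  bind_cols(
    x$summary,
    tibble(
      n_models = length(x$models), horizon = x$settings$horizon,
      n_bootstrap = x$settings$n_boot, seed = x$settings$seed
    )
  )
}

#' Plot all ROC curves of a validation run
#'
#' @param object An `rdr_validation`.
#' @param which `"tdroc"` (default) or `"full"`.
#' @param ... Unused.
#' @return A ggplot overlaying the models' ROC curves.
#' @export
autoplot.rdr_validation <- function(object, which = c("tdroc", "full"), ...) {
  which <- arg_match(which)
  curves <- purrr::map(object$models, function(m) {
    a <- if (which == "tdroc") m$auc_tdroc else m$auc_full
    a$roc |> mutate(model = sprintf("%s (AUC %.2f)", m$name, a$auc))
  }) |>
    bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$fpr, y = .data$tpr,
    colour = .data$model
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a validation report
#'
#' Emits `report.json` (machine-readable: settings, cohort summary,
#' exclusion tally, per-model AUCs and rate tables) and `report.txt`
#' (aligned plain-text tables), plus one ROC-points CSV per model when
#' `roc_csv = TRUE`.
#'
#' @param x An `rdr_validation`.
#' @param dir Output directory (created if needed).
#' @param roc_csv Write per-model ROC point CSVs (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(x, dir, roc_csv = FALSE) {
  stopifnot(inherits(x, "rdr_validation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    settings = x$settings,
    hash = x$hash,
    cohort = as.list(x$summary),
    exclusions = setNames(as.list(x$exclusions$n), x$exclusions$reason),
    models = purrr::map(x$models, function(m) {
      list(
        model_id = m$model_id, engine = m$engine,
        auc_tdroc = as.list(glance(m$auc_tdroc)),
        auc_full_period = as.list(glance(m$auc_full)),
        rate_table = as.data.frame(m$rate_table)
      )
    })
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows"
  )
  writeLines(format_text_report(x), file.path(dir, "report.txt"))
  if (roc_csv) {
    for (m in x$models) {
      readr::write_csv(
        m$auc_tdroc$roc,
        file.path(dir, sprintf("roc_%s.csv", gsub("[^A-Za-z0-9_-]", "_", m$name)))
      )
    }
  }
  invisible(dir)
}

format_text_report <- function(x) {
  s <- x$summary
  lines <- c(
    "Referable-DR risk model validation report",
    sprintf("seed %d | hash %s", x$settings$seed, x$hash),
    sprintf(
      "Cohort: n=%d, person-years=%.1f, events=%d, median follow-up=%.2f y",
      s$n, s$person_years, s$events, s$median_followup
    ),
    sprintf(
      "Exclusions: %s",
      paste(sprintf("%s=%d", x$exclusions$reason, x$exclusions$n), collapse = ", ")
    ),
    ""
  )
  for (m in x$models) {
    td <- m$auc_tdroc
    fl <- m$auc_full
    lines <- c(
      lines,
      sprintf("== %s (%s) ==", m$name, m$model_id),
      sprintf(
        "  AUC at %g y: %.2f (95%% CI %.2f-%.2f); full period: %.2f (95%% CI %.2f-%.2f)",
        td$horizon, td$auc, td$ci_lower, td$ci_upper,
        fl$auc, fl$ci_lower, fl$ci_upper
      ),
      "  Stratum    n  Events  Rate/1000PY      PY",
      sprintf(
        "  %-7s %4d  %6d  %11.1f  %6.1f",
        m$rate_table$stratum, m$rate_table$n, m$rate_table$events,
        m$rate_table$rate_per_1000py, m$rate_table$person_years
      ),
      ""
    )
  }
  lines
}
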