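# Cohort construction: index-screening selection, systemic-visit linkage,
# inclusion/exclusion, follow-up time and event status.
#
# Eligibility requires at least three screening episodes: the first two
# define the risk group, the second is the "index" screening at which
# follow-up starts, and at least one later episode determines the outcome.
# Follow-up runs from the index date to the first post-index episode with
# referable DR (event) or to the last recorded episode (censored).

DAYS_PER_YEAR <- 365.25

exclusion_reasons <- function() {
  c(
    "TOO_FEW_SCREENINGS", "INELIGIBLE_GRADES", "RISK_GROUP_BC",
    "NO_SYSTEMIC_MATCH"
  )
}

#' Select the first and index screening episodes per patient
#'
#' A patient needs at least three screening episodes: two to determine the
#' risk group and a third to determine the outcome.  The second recorded
#' episode is the index screening, after which follow-up commences; later
#' grades never change the choice of index.
#'
#' @param screenings Screening table (`patient_id`, `date`, grade columns);
#'   dates must be unique within a patient.
#' @return A tibble with one row per patient: `patient_id`, `n_screenings`,
#'   `first_date`, `index_date` and a `rejection` column that is `NA` for
#'   patients with at least three episodes and `"TOO_FEW_SCREENINGS"`
#'   otherwise (with `NA` dates).
#' @export
select_index <- function(screenings) {
  check_screenings(screenings)
  screenings |>
    group_by(.data$patient_id) |>
    arrange(.data$date, .by_group = TRUE) |>
    summarise(
      n_screenings = n(),
      first_date = .data$date[1],
      index_date = if (n() >= 2) .data$date[2] else .data$date[NA_integer_],
      .groups = "drop"
    ) |>
    mutate(
      rejection = if_else(.data$n_screenings >= 3, NA_character_,
        "TOO_FEW_SCREENINGS"
      ),
      first_date = if_else(is.na(.data$rejection), .data$first_date,
        as.Date(NA)
      ),
      index_date = if_else(is.na(.data$rejection), .data$index_date,
        as.Date(NA)
      )
    )
}

#' Link the systemic visit feeding each patient's risk scores
#'
#' Covariates are drawn from the most recent systemic visit at or before the
#' index screening, no older than `window_days`, at which a complete set of
#' the variables required by the models was measured.  Visits after the
#' index screening are never used.
#'
#' @param index Tibble with `patient_id` and `index_date` (e.g. from
#'   [select_index()], rejected rows removed).
#' @param visits Systemic-visit table with `patient_id`, `date` and
#'   measurement columns.
#' @param window_days Maximum age, in days, of the linked visit relative to
#'   the index date (default 180).
#' @param required_vars Variables that must all be non-missing at the linked
#'   visit; defaults to HbA1c, total cholesterol and systolic BP.
#' @return `index` with the linked visit's measurement columns appended, a
#'   `systemic_date` column, and `rejection = "NO_SYSTEMIC_MATCH"` (with NA
#'   measurements) where no qualifying visit exists.
#' @export
link_systemic <- function(index, visits, window_days = 180,
                          required_vars = c("hba1c_pct", "total_cholesterol", "sbp")) {
  stopifnot(all(c("patient_id", "index_date") %in% names(index)))
  check_visits(visits, required_vars)
  value_cols <- setdiff(names(visits), c("patient_id", "date"))
  linked <- index |>
    select("patient_id", "index_date") |>
    left_join(visits, by = "patient_id", relationship = "many-to-many") |>
    filter(
      !is.na(.data$date),
      .data$date <= .data$index_date,
      .data$date >= .data$index_date - window_days
    ) |>
    filter(if_all(all_of(required_vars), ~ !is.na(.x))) |>
    group_by(.data$patient_id) |>
    slice_max(.data$date, n = 1, with_ties = FALSE) |>
    ungroup() |>
    rename(systemic_date = "date") |>
    select(-"index_date")
  index |>
    left_join(linked, by = "patient_id") |>
    mutate(rejection = if_else(is.na(.data$systemic_date),
      "NO_SYSTEMIC_MATCH", NA_character_
    ))
}

#' Build the analysis cohort
#'
#' Runs the full inclusion pipeline: at least three screening episodes;
#' risk group from the first two episodes in A or D-I (B and C are excluded
#' by design, and any R2/R3, maculopathy or ungradable eye at either of the
#' first two screenings is ineligible); a complete systemic visit within the
#' linkage window before the index screening.  For included patients,
#' follow-up runs from the index date to the first post-index episode with
#' referable DR (`event = 1`) or to the last recorded episode (`event = 0`).
#' Post-index episodes in which both eyes are ungradable cannot reveal RDR
#' and are skipped for event detection, but the last of them still anchors
#' censoring.
#'
#' @param patients Patient table: `patient_id`, `sex`, `birth_year`,
#'   `diabetes_type`, `diagnosis_date`.
#' @param screenings Screening table as in [screen_rdr()], plus
#'   `patient_id` and `date`.
#' @param visits Systemic-visit table as in [link_systemic()].
#' @param window_days,required_vars Passed to [link_systemic()].
#' @return A tibble of class `rdr_cohort`, one row per included patient:
#'   identifiers, `risk_group`, `index_category` (DR category at the index
#'   screening), index-date covariates (linked systemic values, age,
#'   diabetes duration in years floored at 0), `followup_years`, `event`
#'   and `event_or_censor_date`.  The exclusion tally is attached as
#'   attribute `"exclusions"` (a tibble of reason counts) and the
#'   per-patient exclusion log as attribute `"excluded_patients"`; see
#'   [exclusion_tally()].
#' @export
build_cohort <- function(patients, screenings, visits, window_days = 180,
                         required_vars = c("hba1c_pct", "total_cholesterol", "sbp")) {
  check_patients(patients)
  check_screenings(screenings)
  ids_without_patient <- setdiff(
    unique(screenings$patient_id),
    patients$patient_id
  )
  if (length(ids_without_patient)) {
    abort(sprintf(
      "Screenings reference %d patient id(s) absent from `patients`.",
      length(ids_without_patient)
    ))
  }
  screenings <- screenings |> arrange(.data$patient_id, .data$date)

  idx <- select_index(screenings)
  rejected <- idx |>
    filter(!is.na(.data$rejection)) |>
    select("patient_id", reason = "rejection")
  idx <- idx |> filter(is.na(.data$rejection))

  # risk group from first two episodes
  firsts <- screenings |>
    semi_join(idx, by = "patient_id") |>
    group_by(.data$patient_id) |>
    slice_min(.data$date, n = 2, with_ties = FALSE) |>
    mutate(rank = row_number(.data$date)) |>
    ungroup()
  first_ep <- firsts |> filter(.data$rank == 1) |> arrange(.data$patient_id)
  index_ep <- firsts |> filter(.data$rank == 2) |> arrange(.data$patient_id)
  rg <- classify_risk_group(first_ep, index_ep) |>
    mutate(index_category = screen_category(index_ep)$dr_category)

  rejected <- bind_rows(
    rejected,
    rg |>
      filter(.data$risk_group == "INELIGIBLE") |>
      transmute(.data$patient_id, reason = "INELIGIBLE_GRADES"),
    rg |>
      filter(.data$excluded) |>
      transmute(.data$patient_id, reason = "RISK_GROUP_BC")
  )
  rg <- rg |> filter(.data$risk_group != "INELIGIBLE", !.data$excluded)

  idx <- idx |> semi_join(rg, by = "patient_id")

  # systemic linkage
  linked <- link_systemic(idx, visits,
    window_days = window_days,
    required_vars = required_vars
  )
  rejected <- bind_rows(
    rejected,
    linked |>
      filter(!is.na(.data$rejection)) |>
      transmute(.data$patient_id, reason = "NO_SYSTEMIC_MATCH")
  )
  linked <- linked |> filter(is.na(.data$rejection)) |> select(-"rejection")

  # follow-up and outcome from post-index episodes
  post <- screenings |>
    semi_join(linked, by = "patient_id") |>
    left_join(linked |> select("patient_id", "index_date"), by = "patient_id") |>
    filter(.data$date > .data$index_date) |>
    screen_rdr(on_ungradable = "na")
  outcome <- post |>
    group_by(.data$patient_id) |>
    summarise(
      event = as.integer(any(.data$rdr, na.rm = TRUE)),
      event_or_censor_date = if (any(.data$rdr, na.rm = TRUE)) {
        min(.data$date[!is.na(.data$rdr) & .data$rdr])
      } else {
        max(.data$date)
      },
      .groups = "drop"
    )

  cohort <- linked |>
    inner_join(outcome, by = "patient_id") |>
    inner_join(rg |> select("patient_id", "risk_group", "index_category"),
      by = "patient_id"
    ) |>
    inner_join(patients, by = "patient_id") |>
    mutate(
      followup_years = as.numeric(.data$event_or_censor_date - .data$index_date) /
        DAYS_PER_YEAR,
      duration_years = pmax(
        0,
        as.numeric(.data$index_date - .data$diagnosis_date) / DAYS_PER_YEAR
      ),
      age_years = as.integer(format(.data$index_date, "%Y")) - .data$birth_year
    ) |>
    arrange(.data$patient_id) |>
    select(
      "patient_id", "index_date", "risk_group", "index_category",
      "sex", "birth_year", "age_years", "diabetes_type", "diagnosis_date",
      "duration_years", "systemic_date", everything()
    )
  if ("hba1c_pct" %in% names(cohort) && !"hba1c_mmol_mol" %in% names(cohort)) {
    cohort <- cohort |> mutate(hba1c_mmol_mol = hba1c_to_mmol(.data$hba1c_pct))
  }

  rejected <- rejected |> arrange(.data$patient_id)
  tally <- tibble(reason = exclusion_reasons()) |>
    left_join(count(rejected, .data$reason), by = "reason") |>
    mutate(n = coalesce(.data$n, 0L))
  structure(
    cohort,
    class = c("rdr_cohort", class(tibble())),
    exclusions = tally,
    excluded_patients = rejected
  )
}

#' Exclusion tally of a built cohort
#'
#' @param cohort A cohort from [build_cohort()].
#' @param patients Logical; return the per-patient exclusion log instead of
#'   the per-reason tally.
#' @return A tibble of exclusion reasons and counts (or patient ids).
#' @export
exclusion_tally <- function(cohort, patients = FALSE) {
  if (patients) attr(cohort, "excluded_patients") else attr(cohort, "exclusions")
}

#' Summarise follow-up of a cohort
#'
#' @param cohort A cohort from [build_cohort()] (or any tibble with
#'   `followup_years` and `event`).
#' @return One-row tibble: `n`, `person_years`, `events`,
#'   `median_followup`, `min_followup`, `max_followup`.
#' @export
followup_summary <- function(cohort) {
  if (nrow(cohort) == 0) abort("Cannot summarise an empty cohort.")
  tibble(
    n = nrow(cohort),
    person_years = sum(cohort$followup_years),
    events = sum(cohort$event),
    median_followup = median(cohort$followup_years),
    min_followup = min(cohort$followup_years),
    max_followup = max(cohort$followup_years)
  )
}

#' Convert HbA1c between percentage (DCCT) and mmol/mol (IFCC) units
#'
#' @param pct HbA1c in % units.
#' @param mmol_mol HbA1c in mmol/mol.
#' @return The converted values.
#' @export
#' @examples
#' hba1c_to_mmol(6.8)
hba1c_to_mmol <- function(pct) (pct - 2.15) * 10.929

#' @rdname hba1c_to_mmol
#' @export
hba1c_to_pct <- function(mmol_mol) mmol_mol / 10.929 + 2.15

# Input validation ------------------------------------------------------------

check_screenings <- function(screenings, call = rlang::caller_env()) {
  need <- c("patient_id", "date", grade_cols)
  missing_cols <- setdiff(need, names(screenings))
  if (length(missing_cols)) {
    abort(sprintf(
      "Screening table is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ), call = call)
  }
  if (!inherits(screenings$date, "Date")) {
    abort("Screening `date` must be a Date column.", call = call)
  }
  dup <- screenings |>
    count(.data$patient_id, .data$date) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "%d patient(s) have duplicate screening dates; dates must be unique per patient.",
      length(unique(dup$patient_id))
    ), call = call)
  }
  check_grade_range(screenings, call = call)
  invisible(screenings)
}

check_visits <- function(visits, required_vars, call = rlang::caller_env()) {
  need <- c("patient_id", "date", required_vars)
  missing_cols <- setdiff(need, names(visits))
  if (length(missing_cols)) {
    abort(sprintf(
      "Visit table is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ), call = call)
  }
  if (!inherits(visits$date, "Date")) {
    abort("Visit `date` must be a Date column.", call = call)
  }
  invisible(visits)
}

check_patients <- function(patients, call = rlang::caller_env()) {
  need <- c("patient_id", "sex", "birth_year", "diabetes_type", "diagnosis_date")
  missing_cols <- setdiff(need, names(patients))
  if (length(missing_cols)) {
    abort(sprintf(
      "Patient table is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ), call = call)
  }
  if (anyDuplicated(patients$patient_id)) {
    abort("Patient ids must be unique in `patients`.", call = call)
  }
  invisible(patients)
}
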