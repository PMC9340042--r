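# Fixture builders and independent oracles shared across the test files.

# One screening episode from per-eye grade strings, e.g. ep("R1M0", "R0M0").
# "--" marks an ungradable eye.
ep <- function(right, left, patient_id = NULL, date = NULL) {
  parse_eye <- function(s) {
    if (s == "--") {
      return(c(NA_integer_, NA_integer_))
    }
    c(
      as.integer(substr(s, 2, 2)),
      as.integer(substr(s, 4, 4))
    )
  }
  r <- parse_eye(right)
  l <- parse_eye(left)
  out <- tibble::tibble(
    r_right = r[1], m_right = r[2], r_left = l[1], m_left = l[2]
  )
  if (!is.null(patient_id)) out <- tibble::add_column(out, patient_id = patient_id, .before = 1)
  if (!is.null(date)) out <- tibble::add_column(out, date = as.Date(date), .after = "patient_id")
  out
}

# A screening stream for one patient: grades is a list of c(right, left)
# grade strings, one per annual episode starting at `start`.
screening_stream <- function(patient_id, grades, start = "2006-01-01") {
  dates <- as.Date(start) + round((seq_along(grades) - 1) * 365.25)
  dplyr::bind_rows(lapply(seq_along(grades), function(i) {
    ep(grades[[i]][1], grades[[i]][2], patient_id = patient_id, date = dates[i])
  }))
}

# A complete systemic visit record.
visit <- function(patient_id, date, hba1c_pct = 6.8, total_cholesterol = 5.0,
                  sbp = 136, dbp = 78, bmi = 31, hdl = 1.2, ldl = 2.4,
                  triglycerides = 3.2) {
  tibble::tibble(
    patient_id = patient_id, date = as.Date(date),
    hba1c_pct = hba1c_pct, total_cholesterol = total_cholesterol,
    sbp = sbp, dbp = dbp, bmi = bmi, hdl = hdl, ldl = ldl,
    triglycerides = triglycerides
  )
}

patient_row <- function(patient_id, birth_year = 1945,
                        diagnosis_date = "2004-01-01", sex = "M") {
  tibble::tibble(
    patient_id = patient_id, sex = sex, birth_year = birth_year,
    diabetes_type = "type2", diagnosis_date = as.Date(diagnosis_date)
  )
}

# Exhaustive pairwise Mann-Whitney AUC: the brute-force oracle against which
# the production estimators are checked.  Ties count one half.
brute_force_auc <- function(case_scores, control_scores) {
  total <- 0
  for (ci in case_scores) {
    for (co in control_scores) {
      total <- total + (ci > co) + 0.5 * (ci == co)
    }
  }
  total / (length(case_scores) * length(control_scores))
}

# Random survival samples with no censoring before the horizon: every
# subject either has an event by the horizon or is followed beyond it.
samples_no_early_censoring <- function(n, horizon = 2) {
  t_event <- rexp(n, rate = 0.4)
  event <- as.integer(t_event <= horizon)
  time <- ifelse(event == 1, t_event, horizon + runif(n, 0.01, 3))
  tibble::tibble(
    score = rnorm(n),
    followup_years = time,
    event = event
  )
}
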