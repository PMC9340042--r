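# Retinopathy grading logic: R/M scale, the referable-DR outcome, and the
# two-screening risk-group classification.
#
# Grades follow the English screening-programme scale: R0 (no retinopathy),
# R1 (mild/background non-proliferative DR), R2 (pre-proliferative DR),
# R3 (proliferative DR); maculopathy M0/M1.  "Mild/background DR" means R1
# with M0; "no DR" means R0 with M0.  An ungradable eye is coded as NA in
# both its R and M columns, never as R0M0.

#' Risk-group labels
#'
#' Labels for the risk groups defined by per-eye R0/R1 status at the first
#' two screenings, plus `INELIGIBLE` for any combination involving R2/R3,
#' maculopathy, or an ungradable eye at either screening.  Groups B and C
#' (mild DR at the first screening regressing to none at the second) are
#' defined but excluded from risk scoring.
#'
#' @return Character vector of the eleven labels in classification order.
#' @export
#' @examples
#' risk_group_levels()
risk_group_levels <- function() {
  c("A", "B", "C", "D", "E", "F", "G", "H", "I", "INELIGIBLE")
}

#' Which risk groups are excluded by design?
#'
#' Groups B and C capture apparent regression of mild DR between the two
#' defining screenings; the screening-only grade model carries no score for
#' them, so patients in these groups cannot be risk-scored and are excluded
#' from the analysis cohort.
#'
#' @param label Character vector of risk-group labels.
#' @return Logical vector, `TRUE` where the label is B or C.
#' @export
risk_group_excluded <- function(label) {
  as.character(label) %in% c("B", "C")
}

dr_category_levels <- function() {
  c("NO_DR", "MILD_ONE_EYE", "MILD_BOTH_EYES", "OTHER")
}

# Vectorised eye-level helpers ------------------------------------------------

eye_gradable <- function(r, m) !is.na(r) & !is.na(m)

eye_referable <- function(r, m) eye_gradable(r, m) & (m == 1L | r >= 2L)

eye_no_dr <- function(r, m) eye_gradable(r, m) & r == 0L & m == 0L

eye_mild <- function(r, m) eye_gradable(r, m) & r == 1L & m == 0L

check_grade_range <- function(df, call = rlang::caller_env()) {
  for (col in c("r_right", "r_left")) {
    v <- df[[col]]
    if (any(!is.na(v) & !(v %in% 0:3))) {
      abort(sprintf("Column `%s` must contain grades 0-3 or NA.", col), call = call)
    }
  }
  for (col in c("m_right", "m_left")) {
    v <- df[[col]]
    if (any(!is.na(v) & !(v %in% 0:1))) {
      abort(sprintf("Column `%s` must contain 0, 1 or NA.", col), call = call)
    }
  }
  half <- (is.na(df$r_right) != is.na(df$m_right)) |
    (is.na(df$r_left) != is.na(df$m_left))
  if (any(half)) {
    abort("An eye must have both R and M grades or neither (ungradable).", call = call)
  }
  invisible(df)
}

grade_cols <- c("r_right", "m_right", "r_left", "m_left")

check_grade_cols <- function(df, call = rlang::caller_env()) {
  missing_cols <- setdiff(grade_cols, names(df))
  if (length(missing_cols)) {
    abort(sprintf(
      "Screening table is missing grade column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ), call = call)
  }
  check_grade_range(df, call = call)
}

# Episode-level classification -----------------------------------------------

#' Flag referable diabetic retinopathy (RDR) for screening episodes
#'
#' RDR — the screening programme's referral trigger — is present when any
#' gradable eye shows maculopathy (M1, at any R level) or retinopathy at
#' R2 (pre-proliferative) or R3 (proliferative).  R0 with M1, an unusual
#' combination, is treated as referable: maculopathy triggers referral
#' regardless of the R level.
#'
#' @param screenings Data frame of screening episodes with integer grade
#'   columns `r_right`, `m_right`, `r_left`, `m_left` (R in 0-3, M in 0-1;
#'   an ungradable eye is `NA` in both of its columns).
#' @param on_ungradable What to do with an episode in which both eyes are
#'   ungradable: `"error"` (default) or `"na"` to return `NA` for it.
#' @return The input as a tibble with a logical `rdr` column appended.
#' @export
#' @examples
#' eps <- tibble::tibble(
#'   r_right = c(1L, 0L, 0L), m_right = c(1L, 0L, 0L),
#'   r_left  = c(0L, 0L, 2L), m_left  = c(0L, 0L, 0L)
#' )
#' screen_rdr(eps)$rdr  # TRUE FALSE TRUE
screen_rdr <- function(screenings, on_ungradable = c("error", "na")) {
  on_ungradable <- arg_match(on_ungradable)
  check_grade_cols(screenings)
  right_ok <- eye_gradable(screenings$r_right, screenings$m_right)
  left_ok <- eye_gradable(screenings$r_left, screenings$m_left)
  none <- !right_ok & !left_ok
  if (any(none) && on_ungradable == "error") {
    abort(sprintf(
      "%d episode(s) have no gradable eye; RDR status is undefined for them.",
      sum(none)
    ))
  }
  rdr <- (right_ok & eye_referable(screenings$r_right, screenings$m_right)) |
    (left_ok & eye_referable(screenings$r_left, screenings$m_left))
  rdr[none] <- NA
  as_tibble(screenings) |> mutate(rdr = rdr)
}

#' Classify an episode's DR category for risk grouping
#'
#' Assigns each episode to one of four categories used by the two-screening
#' risk groups: `NO_DR` (both eyes R0M0), `MILD_ONE_EYE` (exactly one eye
#' R1M0, the other R0M0), `MILD_BOTH_EYES` (both eyes R1M0), or `OTHER`
#' (any combination involving R2/R3 or maculopathy).  Risk grouping needs
#' both-eye status, so an episode with an ungradable eye gets `NA`, which
#' [classify_risk_group()] maps to `INELIGIBLE`.
#'
#' @inheritParams screen_rdr
#' @return The input as a tibble with a factor `dr_category` column
#'   (levels `NO_DR`, `MILD_ONE_EYE`, `MILD_BOTH_EYES`, `OTHER`).
#' @export
#' @examples
#' eps <- tibble::tibble(
#'   r_right = c(0L, 1L, 1L), m_right = c(0L, 0L, 1L),
#'   r_left  = c(0L, 1L, 0L), m_left  = c(0L, 0L, 0L)
#' )
#' screen_category(eps)$dr_category  # NO_DR MILD_BOTH_EYES OTHER
screen_category <- function(screenings) {
  check_grade_cols(screenings)
  r_r <- screenings$r_right
  m_r <- screenings$m_right
  r_l <- screenings$r_left
  m_l <- screenings$m_left
  both_gradable <- eye_gradable(r_r, m_r) & eye_gradable(r_l, m_l)
  no_r <- eye_no_dr(r_r, m_r)
  no_l <- eye_no_dr(r_l, m_l)
  mild_r <- eye_mild(r_r, m_r)
  mild_l <- eye_mild(r_l, m_l)
  cat <- rep(NA_character_, nrow(screenings))
  cat[both_gradable] <- "OTHER"
  cat[both_gradable & no_r & no_l] <- "NO_DR"
  cat[both_gradable & ((mild_r & no_l) | (no_r & mild_l))] <- "MILD_ONE_EYE"
  cat[both_gradable & mild_r & mild_l] <- "MILD_BOTH_EYES"
  as_tibble(screenings) |>
    mutate(dr_category = factor(cat, levels = dr_category_levels()))
}

# Mapping from (category at first screening, category at index screening) to
# risk-group label, over the 3x3 grid of eligible categories.  Rows = first
# screening, columns = second (index) screening.
risk_group_grid <- function() {
  m <- matrix(
    c(
      "A", "D", "G",
      "B", "E", "H",
      "C", "F", "I"
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(
      first = c("NO_DR", "MILD_ONE_EYE", "MILD_BOTH_EYES"),
      second = c("NO_DR", "MILD_ONE_EYE", "MILD_BOTH_EYES")
    )
  )
  m
}

#' Classify the two-screening risk group
#'
#' Maps the DR categories at the first two screenings onto the risk groups:
#' A (no DR at both), D/G (new mild DR in one/both eyes at the second),
#' E/I (mild DR in one/both eyes persisting), F/H (mild DR changing between
#' one and both eyes), and B/C (mild DR at the first screening, none at the
#' second — defined but excluded from scoring).  Any `OTHER` category —
#' R2/R3, maculopathy, or an ungradable eye — at either screening makes the
#' patient `INELIGIBLE`.
#'
#' @param first,second Data frames of the first and second (index) screening
#'   episodes, row-aligned (one patient per row), each with the grade columns
#'   of [screen_rdr()] and optionally `patient_id` and `date` columns, which
#'   are checked for consistency and ordering when present in both inputs.
#' @return A tibble with one row per patient: `risk_group` (factor over
#'   [risk_group_levels()]) and `excluded` (logical; `TRUE` for B and C),
#'   preceded by `patient_id` when available.
#' @export
#' @examples
#' first <- tibble::tibble(r_right = 0L, m_right = 0L, r_left = 0L, m_left = 0L)
#' second <- tibble::tibble(r_right = 1L, m_right = 0L, r_left = 0L, m_left = 0L)
#' classify_risk_group(first, second)$risk_group  # D
classify_risk_group <- function(first, second) {
  if (nrow(first) != nrow(second)) {
    abort("`first` and `second` must have the same number of rows.")
  }
  if ("patient_id" %in% names(first) && "patient_id" %in% names(second) &&
    any(first$patient_id != second$patient_id)) {
    abort("`first` and `second` must be row-aligned on the same patients.")
  }
  if ("date" %in% names(first) && "date" %in% names(second) &&
    any(!(first$date < second$date))) {
    abort("Each first screening must predate the second screening.")
  }
  cat1 <- screen_category(first)$dr_category
  cat2 <- screen_category(second)$dr_category
  grid <- risk_group_grid()
  label <- rep("INELIGIBLE", length(cat1))
  ok <- !is.na(cat1) & !is.na(cat2) & cat1 != "OTHER" & cat2 != "OTHER"
  label[ok] <- grid[cbind(as.character(cat1[ok]), as.character(cat2[ok]))]
  out <- tibble(
    risk_group = factor(label, levels = risk_group_levels()),
    excluded = risk_group_excluded(label)
  )
  if ("patient_id" %in% names(first)) {
    out <- bind_cols(tibble(patient_id = first$patient_id), out)
  }
  out
}

#' Enumerate all two-eye grade combinations
#'
#' Builds the full grid of per-episode eye-grade combinations (all R0-R3 by
#' M0-M1 pairs for two eyes, 64 combinations), mainly for exhaustiveness
#' checks of the grading logic.
#'
#' @return A tibble with 64 rows and the four grade columns.
#' @export
enumerate_episode_grades <- function() {
  eye <- tidyr::expand_grid(r = 0:3, m = 0:1)
  tidyr::expand_grid(
    right = seq_len(nrow(eye)),
    left = seq_len(nrow(eye))
  ) |>
    transmute(
      r_right = eye$r[.data$right], m_right = eye$m[.data$right],
      r_left = eye$r[.data$left], m_left = eye$m[.data$left]
    )
}
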