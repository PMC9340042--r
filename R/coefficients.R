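# Coefficient sets: externally configured risk models.
#
# A coefficient set names a model and carries (i) continuous terms
# (variable, optional transform and centring, beta), (ii) an optional
# categorical term keyed on a factor covariate such as the risk group, and
# (iii) an optional baseline survival specification (exponential, Weibull
# or tabulated).  The published Icelandic and Gloucester coefficient tables
# are not redistributed here; the sets shipped under
# inst/extdata/coefficients are synthetic, illustrative values.

#' Construct and validate a coefficient set
#'
#' @param model_id Name of the model.
#' @param terms List of continuous terms, each a list with `variable`,
#'   `beta`, and optionally `transform` (`"identity"` or `"log"`) and
#'   `center` (value subtracted from the — possibly transformed — covariate
#'   before multiplying by `beta`).
#' @param categorical Optional categorical term: a list with `variable`
#'   (name of a factor/character covariate, e.g. `"risk_group"`) and
#'   `levels` (named list mapping levels to coefficient values).  A record
#'   whose level has no entry cannot be scored.
#' @param baseline Optional baseline survival S0(t): a list with
#'   `family = "exponential"` (`rate`), `family = "weibull"` (`shape`,
#'   `scale`; S0(t) = exp(-(t/scale)^shape)), or `family = "table"`
#'   (`time`, `surv` vectors; S0 interpolated linearly, no extrapolation
#'   beyond the last tabulated time).
#' @param combine_mode How the linear predictor combines with S0:
#'   `"PH_POWER"` (default), the proportional-hazards form S0(t)^exp(lp);
#'   or `"STATED_MULTIPLICATIVE"`, min(1, S0(t) * exp(lp)).
#' @return An object of class `coefficient_set`.
#' @export
#' @examples
#' cs <- coefficient_set(
#'   "demo",
#'   terms = list(list(variable = "hba1c_pct", beta = 0.3, center = 6.8)),
#'   baseline = list(family = "exponential", rate = 0.02)
#' )
#' survival_probability(2, lp = 0, coefs = cs)
coefficient_set <- function(model_id, terms = list(), categorical = NULL,
                            baseline = NULL,
                            combine_mode = c("PH_POWER", "STATED_MULTIPLICATIVE")) {
  combine_mode <- arg_match(combine_mode)
  if (!is.character(model_id) || length(model_id) != 1 || !nzchar(model_id)) {
    abort("`model_id` must be a non-empty string.")
  }
  terms <- purrr::map(terms, validate_term)
  if (!is.null(categorical)) categorical <- validate_categorical(categorical)
  if (!is.null(baseline)) baseline <- validate_baseline(baseline)
  structure(
    list(
      model_id = model_id, terms = terms, categorical = categorical,
      baseline = baseline, combine_mode = combine_mode
    ),
    class = "coefficient_set"
  )
}

validate_term <- function(term) {
  if (is.null(term$variable) || is.null(term$beta)) {
    abort("Each term needs `variable` and `beta`.")
  }
  if (!is.numeric(term$beta) || length(term$beta) != 1 || !is.finite(term$beta)) {
    abort(sprintf("Term `%s`: `beta` must be a single finite number.", term$variable))
  }
  term$transform <- term$transform %||% "identity"
  if (!term$transform %in% c("identity", "log")) {
    abort(sprintf(
      "Term `%s`: unknown transform `%s` (use \"identity\" or \"log\").",
      term$variable, term$transform
    ))
  }
  term$center <- term$center %||% 0
  if (!is.numeric(term$center) || length(term$center) != 1) {
    abort(sprintf("Term `%s`: `center` must be a single number.", term$variable))
  }
  term
}

validate_categorical <- function(categorical) {
  if (is.null(categorical$variable) || is.null(categorical$levels)) {
    abort("`categorical` needs `variable` and a named `levels` map.")
  }
  lv <- categorical$levels
  if (is.null(names(lv)) || any(!nzchar(names(lv)))) {
    abort("`categorical$levels` must be a fully named list of coefficients.")
  }
  vals <- unlist(lv, use.names = FALSE)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("`categorical$levels` values must all be finite numbers.")
  }
  categorical$levels <- as.list(setNames(as.numeric(vals), names(lv)))
  categorical
}

validate_baseline <- function(baseline) {
  fam <- baseline$family %||% abort("`baseline` needs a `family`.")
  switch(fam,
    exponential = {
      if (is.null(baseline$rate) || baseline$rate < 0) {
        abort("Exponential baseline needs a nonnegative `rate`.")
      }
    },
    weibull = {
      if (is.null(baseline$shape) || is.null(baseline$scale) ||
        baseline$shape <= 0 || baseline$scale <= 0) {
        abort("Weibull baseline needs positive `shape` and `scale`.")
      }
    },
    table = {
      t <- baseline$time
      s <- baseline$surv
      if (is.null(t) || is.null(s) || length(t) != length(s) || length(t) < 2) {
        abort("Tabulated baseline needs `time` and `surv` vectors of equal length >= 2.")
      }
      if (is.unsorted(t, strictly = TRUE)) {
        abort("Tabulated baseline `time` must be strictly increasing.")
      }
      if (any(diff(s) > 1e-12)) {
        abort("Tabulated baseline `surv` must be nonincreasing in time.")
      }
      if (any(s < 0 | s > 1)) abort("Tabulated baseline `surv` must lie in [0, 1].")
      if (t[1] > 0) {
        baseline$time <- c(0, t)
        baseline$surv <- c(1, s)
      } else if (abs(s[1] - 1) > 1e-12) {
        abort("Tabulated baseline must satisfy S0(0) = 1.")
      }
    },
    abort(sprintf(
      "Unknown baseline family `%s` (use exponential, weibull or table).", fam
    ))
  )
  baseline
}

#' Baseline survival S0(t) of a coefficient set
#'
#' @param coefs A [coefficient_set()] with a baseline specification.
#' @param t Vector of nonnegative times (years).
#' @return S0(t), in \[0, 1\].  For a tabulated baseline, times beyond the
#'   last tabulated point raise an extrapolation error.
#' @export
baseline_survival <- function(coefs, t) {
  stopifnot(inherits(coefs, "coefficient_set"))
  b <- coefs$baseline
  if (is.null(b)) {
    abort(sprintf("Model `%s` has no baseline survival specification.", coefs$model_id))
  }
  if (any(t < 0)) abort("Baseline survival is defined for t >= 0 only.")
  switch(b$family,
    exponential = exp(-b$rate * t),
    weibull = exp(-(t / b$scale)^b$shape),
    table = {
      if (any(t > max(b$time) + 1e-12)) {
        abort(sprintf(
          "t = %.3g is beyond the tabulated baseline range (max %.3g); refusing to extrapolate.",
          max(t), max(b$time)
        ))
      }
      approx(b$time, b$surv, xout = pmin(t, max(b$time)), method = "linear")$y
    }
  )
}

#' Read a coefficient set from a YAML or JSON config file
#'
#' The schema mirrors [coefficient_set()]: `model_id`, `combine_mode`,
#' `baseline` (family and parameters), `terms` (list of variable /
#' transform / center / beta) and `categorical` (variable plus a `levels`
#' map).  Validation errors name the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `coefficient_set`.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) abort(sprintf("Coefficient file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$model_id)) {
    abort(sprintf("Config %s: missing `model_id`.", basename(path)))
  }
  coefficient_set(
    model_id = raw$model_id,
    terms = raw$terms %||% list(),
    categorical = raw$categorical,
    baseline = raw$baseline,
    combine_mode = raw$combine_mode %||% "PH_POWER"
  )
}

#' Illustrative coefficient sets shipped with the package
#'
#' Loads one of the synthetic, clearly non-canonical coefficient sets
#' shipped under `inst/extdata/coefficients/`.  These reproduce the
#' *structure* of the published Icelandic and Gloucester models (variables,
#' baseline-survival form, grade-category terms) with made-up values, so
#' the scoring and validation machinery can be exercised end to end.
#'
#' @param which One of `"icelandic"`, `"gloucester_two_grades"`,
#'   `"gloucester_two_grades_systemic"`, `"gloucester_one_grade_systemic"`.
#' @return A `coefficient_set`.
#' @export
#' @examples
#' example_coefficients("icelandic")$model_id
example_coefficients <- function(which = c(
                                   "icelandic", "gloucester_two_grades",
                                   "gloucester_two_grades_systemic",
                                   "gloucester_one_grade_systemic"
                                 )) {
  which <- arg_match(which)
  path <- system.file("extdata", "coefficients", paste0(which, ".yaml"),
    package = "rdrisk", mustWork = TRUE
  )
  read_coefficients(path)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set> %s (%s)\n", x$model_id, x$combine_mode))
  if (length(x$terms)) {
    cat(sprintf(
      "  terms: %s\n",
      paste(purrr::map_chr(x$terms, function(tm) {
        sprintf("%s (beta = %g)", tm$variable, tm$beta)
      }), collapse = ", ")
    ))
  }
  if (!is.null(x$categorical)) {
    cat(sprintf(
      "  categorical: %s over {%s}\n", x$categorical$variable,
      paste(names(x$categorical$levels), collapse = ", ")
    ))
  }
  if (!is.null(x$baseline)) {
    cat(sprintf("  baseline: %s\n", x$baseline$family))
  }
  invisible(x)
}
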