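#' Declarative trial specification
#'
#' A structured definition of an emulated phase 3 trial: arm regimens and line
#' of therapy, biomarker requirement with its 30-day post-treatment-start
#' capture window, strict-eligibility exclusions (comorbidity flags with a
#' 1-year lookback, an ECOG cutoff, organ-dysfunction laboratory thresholds
#' within 3 months before treatment, exclusionary metastasis sites with a
#' 3-month lookback), a standard-dose rule, and the RCT benchmark used for
#' agreement assessment.
#'
#' @param trial_id Identifier string.
#' @param cancer_preset Cancer preset the trial applies to.
#' @param arms List with `treatment` and `control`, each
#'   `list(regimens = <chr>, line = <int>)`.
#' @param biomarker `NULL` or `list(column, required_value, window_after_start
#'   = 30)`.
#' @param strict `NULL` or `list(ecog_max, exclude_comorbidities,
#'   comorbidity_lookback_days = 365, lab_limits, lab_lookback_days = 90,
#'   exclude_met_sites, met_lookback_days = 90)`. `lab_limits` is a named list
#'   with `min`/`max` thresholds (units are the cohort's lab units).
#' @param standard_dose `NULL` or `list(min_first_dose)`.
#' @param benchmark `list(hr, ci_lower, ci_upper, endpoint = "OS",
#'   mos_treatment, mos_control, ...)`; the CI must bracket the HR and exactly
#'   one primary endpoint (`"OS"` or `"PFS"`) is allowed.
#' @param crossover_allowed Logical.
#' @return An object of class `rwe_trial_spec`.
#' @export
trial_spec <- function(trial_id, cancer_preset, arms, biomarker = NULL,
                       strict = NULL, standard_dose = NULL, benchmark,
                       crossover_allowed = FALSE) {
  spec <- structure(list(
    trial_id = trial_id, cancer_preset = cancer_preset, arms = arms,
    biomarker = biomarker, strict = strict, standard_dose = standard_dose,
    benchmark = benchmark, crossover_allowed = isTRUE(crossover_allowed)
  ), class = "rwe_trial_spec")
  validate_trial_spec(spec)
  spec
}

validate_trial_spec <- function(spec) {
  for (arm in c("treatment", "control")) {
    a <- spec$arms[[arm]]
    if (is.null(a$regimens) || is.null(a$line)) {
      stop_config("arm '", arm, "' needs regimens and line of therapy")
    }
  }
  b <- spec$benchmark
  if (is.null(b$hr) || is.null(b$ci_lower) || is.null(b$ci_upper)) {
    stop_config("benchmark must provide hr, ci_lower, ci_upper")
  }
  if (!(b$ci_lower <= b$hr && b$hr <= b$ci_upper)) {
    stop_config("benchmark CI must bracket the benchmark HR")
  }
  endpoint <- b$endpoint %||% "OS"
  if (length(endpoint) != 1 || !endpoint %in% c("OS", "PFS")) {
    stop_config("benchmark endpoint must be exactly one of 'OS' or 'PFS'")
  }
  if (!is.null(spec$biomarker) && is.null(spec$biomarker$column)) {
    stop_config("biomarker requirement needs the cohort column name")
  }
  invisible(spec)
}

#' @export
print.rwe_trial_spec <- function(x, ...) {
  cat("<rwe_trial_spec>", x$trial_id, "(", x$cancer_preset, ")\n")
  cat("  treatment:", paste(x$arms$treatment$regimens, collapse = "/"),
      " vs control:", paste(x$arms$control$regimens, collapse = "/"), "\n")
  cat("  benchmark HR:", x$benchmark$hr, sprintf("(%s-%s)",
      x$benchmark$ci_lower, x$benchmark$ci_upper), x$benchmark$endpoint %||%
        "OS", "\n")
  invisible(x)
}

#' Read or write a trial specification as YAML or JSON
#'
#' @param spec An `rwe_trial_spec`.
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @export
write_trial_spec <- function(spec, path) {
  validate_trial_spec(spec)
  lst <- unclass(spec)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else stop_config("unsupported trial spec extension: .", ext)
  invisible(path)
}

#' @rdname write_trial_spec
#' @export
read_trial_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop_config("unsupported trial spec extension: .", ext)
  do.call(trial_spec, lst)
}

#' Synthetic first-line immunotherapy-style trial for the aNSCLC-like preset
#'
#' A shipped example specification against the synthetic cohort's regimens,
#' with a benchmark HR typical of a positive first-line checkpoint-inhibitor
#' trial. The benchmark numbers are synthetic, chosen to be consistent with
#' the generator's treatment effect (HR 0.7); they are not the results of any
#' actual RCT.
#'
#' @return An `rwe_trial_spec`.
#' @export
example_trial_spec <- function() {
  trial_spec(
    trial_id = "SYNTH-IO-01",
    cancer_preset = "aNSCLC-like",
    arms = list(
      treatment = list(regimens = "combo_regimen", line = 1L),
      control = list(regimens = "control_regimen", line = 1L)
    ),
    biomarker = list(column = "pdl1", required_value = 1,
                     window_after_start = 30),
    strict = list(
      ecog_max = 2,
      exclude_comorbidities = c("comorb_chf", "comorb_renal"),
      comorbidity_lookback_days = 365,
      lab_limits = list(hemoglobin = list(min = 9),
                        creatinine = list(max = 2),
                        bilirubin = list(max = 3)),
      lab_lookback_days = 90,
      exclude_met_sites = "cns",
      met_lookback_days = 90
    ),
    standard_dose = list(min_first_dose = 150),
    benchmark = list(hr = 0.70, ci_lower = 0.58, ci_upper = 0.85,
                     endpoint = "OS", mos_treatment = 17.5,
                     mos_control = 12.5),
    crossover_allowed = FALSE
  )
}
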