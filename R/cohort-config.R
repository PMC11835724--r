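#' Cancer preset parameters
#'
#' Marginal distributions for the four supported metastatic-cancer presets.
#' Scale parameters (`center`/`scale`) are fixed constants used to standardize
#' continuous features before coefficient maps are applied, so a coefficient of
#' 0.1 on `age` always means 0.1 per preset standard deviation.
#'
#' @param preset One of `"aNSCLC-like"`, `"mBC-like"`, `"mPC-like"`,
#'   `"mCRC-like"`.
#' @return A list of preset parameters.
#' @export
cancer_preset <- function(preset = c("aNSCLC-like", "mBC-like", "mPC-like",
                                     "mCRC-like")) {
  preset <- match.arg(preset)
  base <- list(
    name = preset,
    age = list(mean = 68, sd = 9, min = 30, max = 92),
    p_male = 0.55,
    ecog_probs = c(`0` = 0.20, `1` = 0.40, `2` = 0.25, `3` = 0.10, `4` = 0.05),
    labs = list(
      creatinine = list(meanlog = log(0.95), sdlog = 0.25, unit = "mg/dl"),
      hemoglobin = list(mean = 12.5, sd = 1.7, unit = "g/dl"),
      bilirubin  = list(meanlog = log(0.60), sdlog = 0.40, unit = "mg/dl"),
      albumin    = list(mean = 3.9, sd = 0.5, unit = "g/dl")
    ),
    weight = list(mean = 75, sd = 15),                 # kg
    weight_pct_change = list(mean = -3, sd = 5),       # % over the window
    p_biomarker = 0.50,                                # PD-L1-style flag
    p_smoker = 0.55,
    histology_probs = c(adeno = 0.60, squamous = 0.25, other = 0.15),
    year_range = c(2014, 2021),
    time_to_met = list(p_denovo = 0.60, mean_months = 8),
    comorbidity_probs = c(comorb_chf = 0.08, comorb_renal = 0.06),
    p_line1 = 0.85,
    regimens = list(treatment = "combo_regimen", control = "control_regimen"),
    horizon_months = 24,
    baseline_hazard = 0.025
  )
  tweaks <- switch(preset,
    "aNSCLC-like" = list(p_smoker = 0.80, p_biomarker = 0.55,
                         horizon_months = 12, baseline_hazard = 0.055),
    "mBC-like"    = list(p_male = 0.01, baseline_hazard = 0.020),
    "mPC-like"    = list(p_male = 1.00, baseline_hazard = 0.018),
    "mCRC-like"   = list(baseline_hazard = 0.025)
  )
  base[names(tweaks)] <- tweaks
  base
}

# Feature names a coefficient map may reference (columns of the internal
# standardized design matrix).
design_feature_names <- function() {
  c("age", "sex_male", "ecog", "creatinine", "hemoglobin", "bilirubin",
    "albumin", "weight_pct_change", "pdl1", "smoker", "histology_squamous",
    "histology_other", "year_of_dx", "time_to_met", "comorb_chf",
    "comorb_renal")
}

default_treatment_coefs <- function() {
  c("(Intercept)" = 0.45, ecog = -0.70, age = -0.30, albumin = 0.50,
    pdl1 = 1.20, weight_pct_change = 0.40, hemoglobin = 0.30,
    year_of_dx = 0.20)
}

default_outcome_coefs <- function() {
  c(ecog = 0.10, age = 0.06, albumin = -0.08, hemoglobin = -0.045,
    weight_pct_change = -0.08, pdl1 = -0.055, creatinine = 0.033,
    bilirubin = 0.028, smoker = 0.028, time_to_met = -0.028)
}

default_missing_rates <- function() {
  c(ecog = 0.53, creatinine = 0.35, hemoglobin = 0.30, bilirubin = 0.40,
    albumin = 0.45, weight_pct_change = 0.25)
}

#' Configuration of the synthetic cohort generator
#'
#' Defines an EHR-like oncology cohort with a known treatment-assignment model,
#' outcome model and missingness mechanism. Coefficients are on the log-odds
#' (treatment) and log-hazard (outcome) scales and apply to standardized
#' continuous features (fixed preset centers/scales), to raw 0/1 flags, and to
#' the ECOG score per point.
#'
#' @param n_patients Positive patient count.
#' @param cancer_preset One of the four cancer presets.
#' @param treatment_logit_coefs Named numeric vector; may include
#'   `"(Intercept)"`.
#' @param outcome_log_hazard_coefs Named numeric vector of prognostic effects.
#' @param treatment_log_hr Treatment main effect on the log-hazard scale
#'   (negative = protective).
#' @param effect_modification Non-negative attenuation slope: the effective
#'   treatment log-hazard is `treatment_log_hr * max(0, 1 - em * z)` with `z`
#'   the standardized latent risk, so higher-risk patients receive a smaller
#'   benefit and the effect never reverses sign. `0` gives a homogeneous
#'   effect.
#' @param baseline_hazard Baseline event rate per month (> 0); defaults to the
#'   preset value.
#' @param admin_censor_time Administrative censoring time in months.
#' @param dropout_rate Per-month dropout hazard (>= 0).
#' @param missing_rates Named fractions in `[0, 1]` of features to mask.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return An object of class `rwe_cohort_config`.
#' @export
cohort_config <- function(n_patients = 5000,
                          cancer_preset = "aNSCLC-like",
                          treatment_logit_coefs = default_treatment_coefs(),
                          outcome_log_hazard_coefs = default_outcome_coefs(),
                          treatment_log_hr = log(0.7),
                          effect_modification = 0,
                          baseline_hazard = NULL,
                          admin_censor_time = 60,
                          dropout_rate = 0.005,
                          missing_rates = default_missing_rates(),
                          seed = 20260919L) {
  preset <- cancer_preset(cancer_preset)
  cfg <- structure(list(
    n_patients = n_patients,
    cancer_preset = preset$name,
    treatment_logit_coefs = treatment_logit_coefs,
    outcome_log_hazard_coefs = outcome_log_hazard_coefs,
    treatment_log_hr = treatment_log_hr,
    effect_modification = effect_modification,
    baseline_hazard = baseline_hazard %||% preset$baseline_hazard,
    admin_censor_time = admin_censor_time,
    dropout_rate = dropout_rate,
    missing_rates = missing_rates,
    seed = as.integer(seed)
  ), class = "rwe_cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 1 || cfg$n_patients != round(cfg$n_patients)) {
    stop_config("n_patients must be a positive integer count")
  }
  if (!cfg$cancer_preset %in% c("aNSCLC-like", "mBC-like", "mPC-like",
                                "mCRC-like")) {
    stop_config("unknown cancer_preset: ", cfg$cancer_preset)
  }
  if (cfg$baseline_hazard <= 0) stop_config("baseline_hazard must be > 0")
  if (cfg$admin_censor_time <= 0) stop_config("admin_censor_time must be > 0")
  if (cfg$dropout_rate < 0) stop_config("dropout_rate must be >= 0")
  if (cfg$effect_modification < 0) {
    stop_config("effect_modification must be >= 0")
  }
  ok <- design_feature_names()
  for (what in c("treatment_logit_coefs", "outcome_log_hazard_coefs")) {
    nm <- names(cfg[[what]])
    if (is.null(nm) || any(nm == "")) stop_config(what, " must be named")
    bad <- setdiff(nm, c(ok, "(Intercept)"))
    if (length(bad)) {
      stop_config("unknown feature name(s) in ", what, ": ",
                  paste(bad, collapse = ", "))
    }
  }
  maskable <- c("ecog", "creatinine", "hemoglobin", "bilirubin", "albumin",
                "weight_pct_change")
  nm <- names(cfg$missing_rates)
  if (length(cfg$missing_rates)) {
    bad <- setdiff(nm, maskable)
    if (length(bad)) {
      stop_config("missing_rates may not target: ", paste(bad, collapse = ", "))
    }
    if (any(cfg$missing_rates < 0 | cfg$missing_rates > 1)) {
      stop_config("missing_rates values must be in [0, 1]")
    }
  }
  invisible(cfg)
}

#' @export
print.rwe_cohort_config <- function(x, ...) {
  cat("<rwe_cohort_config>\n")
  cat("  preset:", x$cancer_preset, " n:", x$n_patients, " seed:", x$seed, "\n")
  cat("  treatment HR:", round(exp(x$treatment_log_hr), 3),
      " effect modification:", x$effect_modification, "\n")
  cat("  baseline hazard:", x$baseline_hazard, "/month, admin censor:",
      x$admin_censor_time, "months, dropout:", x$dropout_rate, "/month\n")
  invisible(x)
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  for (f in c("treatment_logit_coefs", "outcome_log_hazard_coefs",
              "missing_rates")) {
    out[[f]] <- as.list(out[[f]])
  }
  out
}

config_from_list <- function(lst) {
  for (f in c("treatment_logit_coefs", "outcome_log_hazard_coefs",
              "missing_rates")) {
    lst[[f]] <- unlist(lst[[f]])
  }
  do.call(cohort_config, lst[names(lst) %in% names(formals(cohort_config))])
}

#' Read or write a cohort configuration
#'
#' Configs round-trip losslessly through YAML (`.yaml`/`.yml`) or JSON
#' (`.json`), chosen by file extension.
#'
#' @param cfg A `rwe_cohort_config`.
#' @param path Destination/source file.
#' @return `read_cohort_config` returns the config; `write_cohort_config`
#'   returns `path` invisibly.
#' @export
write_cohort_config <- function(cfg, path) {
  validate_cohort_config(cfg)
  lst <- config_as_list(cfg)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop_config("unsupported config extension: .", ext)
  }
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_config("unsupported config extension: .", ext)
  }
  config_from_list(lst)
}
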