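#' Features a prognostic model is allowed to see
#'
#' The leakage contract for model fitting: the ground-truth linear predictor
#' (`latent_true_risk`), treatment assignment and outcome columns are never in
#' this list, so they cannot reach a fitted model by construction. Race,
#' ethnicity and insurance-type analogues are likewise excluded from prognostic
#' modelling.
#'
#' @return Character vector of permitted feature-column names.
#' @export
model_features <- function() {
  c("age", "sex", "ecog", "creatinine", "hemoglobin", "bilirubin", "albumin",
    "weight_pct_change", "pdl1", "smoker", "histology", "year_of_dx",
    "time_to_met", "comorb_chf", "comorb_renal",
    "creatinine_min", "creatinine_max", "creatinine_slope",
    "hemoglobin_min", "hemoglobin_max", "hemoglobin_slope",
    "bilirubin_min", "bilirubin_max", "bilirubin_slope",
    "albumin_min", "albumin_max", "albumin_slope")
}

# Standardized design matrix used by the generating coefficient maps.
feature_design <- function(patients, preset) {
  std <- function(x, center, scale) (x - center) / scale
  cbind(
    age = std(patients$age, preset$age$mean, preset$age$sd),
    sex_male = as.numeric(patients$sex == "male"),
    ecog = as.numeric(patients$ecog),
    creatinine = std(log(patients$creatinine), preset$labs$creatinine$meanlog,
                     preset$labs$creatinine$sdlog),
    hemoglobin = std(patients$hemoglobin, preset$labs$hemoglobin$mean,
                     preset$labs$hemoglobin$sd),
    bilirubin = std(log(patients$bilirubin), preset$labs$bilirubin$meanlog,
                    preset$labs$bilirubin$sdlog),
    albumin = std(patients$albumin, preset$labs$albumin$mean,
                  preset$labs$albumin$sd),
    weight_pct_change = std(patients$weight_pct_change,
                            preset$weight_pct_change$mean,
                            preset$weight_pct_change$sd),
    pdl1 = patients$pdl1,
    smoker = patients$smoker,
    histology_squamous = as.numeric(patients$histology == "squamous"),
    histology_other = as.numeric(patients$histology == "other"),
    year_of_dx = std(patients$year_of_dx, mean(preset$year_range),
                     diff(preset$year_range) / sqrt(12)),
    time_to_met = std(patients$time_to_met, 3, 6),
    comorb_chf = patients$comorb_chf,
    comorb_renal = patients$comorb_renal
  )
}

apply_coefs <- function(design, coefs) {
  nm <- setdiff(names(coefs), "(Intercept)")
  lp <- if (length(nm)) drop(design[, nm, drop = FALSE] %*% coefs[nm]) else
    rep(0, nrow(design))
  if ("(Intercept)" %in% names(coefs)) lp <- lp + coefs[["(Intercept)"]]
  lp
}

effective_treatment_loghr <- function(cfg, latent_risk) {
  z <- (latent_risk - mean(latent_risk)) / stats::sd(latent_risk)
  cfg$treatment_log_hr * pmax(0, 1 - cfg$effect_modification * z)
}

#' Generate a fully observed synthetic cohort
#'
#' Draws an EHR-like oncology cohort from a known generating model: baseline
#' features from the cancer preset, a confounded Bernoulli treatment
#' assignment with probability `expit(treatment_logit_coefs . x)`, exponential
#' survival with rate `baseline_hazard * exp(outcome_log_hazard_coefs . x +
#' effective_treatment_log_hr * Z)` and observed time the minimum of death,
#' administrative censoring and exponential dropout. The ground-truth linear
#' predictor is retained as `latent_true_risk` for testing only.
#'
#' Longitudinal laboratory, ECOG and weight measurements are emitted in a long
#' `observations` table with integer day stamps relative to the index date.
#'
#' @param config A [cohort_config()].
#' @return An object of class `rwe_cohort`: a list with `patients` (wide
#'   per-patient table), `observations` (long table) and `config`.
#' @export
generate_base_cohort <- function(config) {
  validate_cohort_config(config)
  preset <- cancer_preset(config$cancer_preset)
  n <- config$n_patients
  set.seed(config$seed)

  age <- pmin(pmax(stats::rnorm(n, preset$age$mean, preset$age$sd),
                   preset$age$min), preset$age$max)
  sex <- ifelse(stats::runif(n) < preset$p_male, "male", "female")
  ecog <- sample(0:4, n, replace = TRUE, prob = preset$ecog_probs)
  creatinine <- stats::rlnorm(n, preset$labs$creatinine$meanlog,
                              preset$labs$creatinine$sdlog)
  hemoglobin <- stats::rnorm(n, preset$labs$hemoglobin$mean,
                             preset$labs$hemoglobin$sd)
  bilirubin <- stats::rlnorm(n, preset$labs$bilirubin$meanlog,
                             preset$labs$bilirubin$sdlog)
  albumin <- stats::rnorm(n, preset$labs$albumin$mean, preset$labs$albumin$sd)
  weight0 <- pmax(stats::rnorm(n, preset$weight$mean, preset$weight$sd), 35)
  weight_pct_change <- stats::rnorm(n, preset$weight_pct_change$mean,
                                    preset$weight_pct_change$sd)
  pdl1 <- stats::rbinom(n, 1, preset$p_biomarker)
  smoker <- stats::rbinom(n, 1, preset$p_smoker)
  histology <- sample(names(preset$histology_probs), n, replace = TRUE,
                      prob = preset$histology_probs)
  year_of_dx <- sample(seq(preset$year_range[1], preset$year_range[2]), n,
                       replace = TRUE)
  denovo <- stats::runif(n) < preset$time_to_met$p_denovo
  time_to_met <- ifelse(denovo, 0,
                        stats::rexp(n, 1 / preset$time_to_met$mean_months))
  comorb_chf <- stats::rbinom(n, 1, preset$comorbidity_probs[["comorb_chf"]])
  comorb_renal <- stats::rbinom(n, 1,
                                preset$comorbidity_probs[["comorb_renal"]])
  line_of_therapy <- ifelse(stats::runif(n) < preset$p_line1, 1L, 2L)
  met_cns <- stats::rbinom(n, 1, 0.12)

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, ecog = ecog,
    creatinine = creatinine, hemoglobin = hemoglobin, bilirubin = bilirubin,
    albumin = albumin, weight_baseline = weight0,
    weight_pct_change = weight_pct_change,
    pdl1 = pdl1, smoker = smoker, histology = histology,
    year_of_dx = year_of_dx, time_to_met = time_to_met,
    comorb_chf = comorb_chf, comorb_renal = comorb_renal,
    line_of_therapy = line_of_therapy, met_cns = met_cns,
    stringsAsFactors = FALSE
  )

  X <- feature_design(patients, preset)
  e_true <- expit(apply_coefs(X, config$treatment_logit_coefs))
  treatment <- stats::rbinom(n, 1, e_true)
  lp <- apply_coefs(X, config$outcome_log_hazard_coefs)
  loghr_eff <- effective_treatment_loghr(config, lp)
  rate <- config$baseline_hazard * exp(lp + loghr_eff * treatment)

  t_death <- stats::rexp(n, rate)
  t_drop <- if (config$dropout_rate > 0) {
    stats::rexp(n, config$dropout_rate)
  } else rep(Inf, n)
  time <- pmin(t_death, t_drop, config$admin_censor_time)
  event <- as.integer(t_death <= pmin(t_drop, config$admin_censor_time))

  patients$treatment <- treatment
  patients$regimen <- ifelse(treatment == 1, preset$regimens$treatment,
                             preset$regimens$control)
  patients$treatment_start <- as.integer(round(stats::runif(n, 0, 40)))
  dose <- round(stats::rnorm(n, 200, 25))
  reduced <- stats::runif(n) < 0.10
  dose[reduced] <- round(stats::runif(sum(reduced), 90, 140))
  dose[stats::runif(n) < 0.05] <- NA_real_
  patients$first_dose <- dose
  patients$biomarker_day <- patients$treatment_start +
    as.integer(round(stats::runif(n, -30, 45)))
  patients$met_cns_day <- ifelse(met_cns == 1,
                                 -as.integer(round(stats::runif(n, 5, 160))),
                                 NA_integer_)
  patients$comorb_chf_day <- ifelse(comorb_chf == 1,
                                    -as.integer(round(stats::runif(n, 20, 600))),
                                    NA_integer_)
  patients$comorb_renal_day <- ifelse(comorb_renal == 1,
                                      -as.integer(round(stats::runif(n, 20, 600))),
                                      NA_integer_)
  patients$time <- pmax(time, 1e-6)
  patients$event <- event
  patients$e_true <- e_true
  patients$latent_true_risk <- lp

  cohort <- structure(list(
    patients = patients,
    observations = generate_observations(patients, preset),
    config = config
  ), class = "rwe_cohort")
  cohort
}

# Long observation records consistent with the wide baseline values: for each
# lab the observation closest to the index date carries the baseline value.
generate_observations <- function(patients, preset) {
  n <- nrow(patients)
  labs <- c("creatinine", "hemoglobin", "bilirubin", "albumin")
  obs <- vector("list", length(labs) + 2)
  for (k in seq_along(labs)) {
    lab <- labs[k]
    base_val <- patients[[lab]]
    scale <- stats::sd(base_val)
    n_extra <- sample(0:2, n, replace = TRUE)
    day0 <- as.integer(round(stats::runif(n, -60, 10)))
    rows <- list(data.frame(patient_id = patients$patient_id, feature = lab,
                            day = day0, value = base_val,
                            stringsAsFactors = FALSE))
    for (j in 1:2) {
      has <- n_extra >= j
      if (!any(has)) next
      day <- as.integer(round(stats::runif(sum(has), -120, 45)))
      val <- base_val[has] + stats::rnorm(sum(has), 0, 0.10 * scale)
      rows[[j + 1]] <- data.frame(patient_id = patients$patient_id[has],
                                  feature = lab, day = day, value = val,
                                  stringsAsFactors = FALSE)
    }
    obs[[k]] <- do.call(rbind, rows)
  }
  # weight: an early and a late in-window measurement realizing the % change
  w_day0 <- as.integer(round(stats::runif(n, -85, -40)))
  w_day1 <- as.integer(round(stats::runif(n, 0, 25)))
  obs[[length(labs) + 1]] <- data.frame(
    patient_id = rep(patients$patient_id, 2), feature = "weight",
    day = c(w_day0, w_day1),
    value = c(patients$weight_baseline,
              patients$weight_baseline * (1 + patients$weight_pct_change / 100)),
    stringsAsFactors = FALSE
  )
  obs[[length(labs) + 2]] <- data.frame(
    patient_id = patients$patient_id, feature = "ecog",
    day = -as.integer(round(stats::runif(n, 0, 30))),
    value = as.numeric(patients$ecog), stringsAsFactors = FALSE
  )
  out <- do.call(rbind, obs)
  out[order(out$patient_id, out$feature, out$day), , drop = FALSE]
}

#' Mask features missing-at-random
#'
#' Masks each feature named in `config$missing_rates` with probability given by
#' a logistic model in age and ECOG (ECOG's own missingness depends on age
#' only), calibrated so the marginal masked fraction matches the configured
#' rate. Masked wide-table cells become `NA` and the matching observation rows
#' are removed. Outcome and treatment columns can never be masked.
#'
#' @param cohort An `rwe_cohort`.
#' @param config The cohort config carrying `missing_rates`; defaults to the
#'   cohort's own config.
#' @return The cohort with missingness applied.
#' @export
inject_missingness <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "rwe_cohort"))
  rates <- config$missing_rates
  if (any(names(rates) %in% c("time", "event", "treatment"))) {
    stop_config("time/event/treatment columns can never be masked")
  }
  validate_cohort_config(config)
  if (!length(rates) || all(rates == 0)) return(cohort)
  p <- cohort$patients
  preset <- cancer_preset(config$cancer_preset)
  z_age <- (p$age - preset$age$mean) / preset$age$sd
  ecog_hi <- as.numeric(p$ecog >= 2)
  set.seed(child_seed(config$seed, 101L))
  drop_obs <- list()
  for (feat in names(rates)) {
    rate <- rates[[feat]]
    if (rate == 0) next
    if (rate >= 1) {
      miss <- rep(TRUE, nrow(p))
    } else {
      lin <- if (feat == "ecog") 0.5 * z_age else 0.5 * z_age + 0.6 * ecog_hi
      a0 <- stats::uniroot(function(a) mean(expit(a + lin)) - rate,
                           c(-20, 20))$root
      miss <- stats::runif(nrow(p)) < expit(a0 + lin)
    }
    p[[feat]][miss] <- NA
    obs_feat <- if (feat == "weight_pct_change") "weight" else feat
    drop_obs[[feat]] <- data.frame(patient_id = p$patient_id[miss],
                                   feature = obs_feat,
                                   stringsAsFactors = FALSE)
  }
  if (length(drop_obs)) {
    dd <- do.call(rbind, drop_obs)
    key <- paste(cohort$observations$patient_id, cohort$observations$feature)
    cohort$observations <-
      cohort$observations[!key %in% paste(dd$patient_id, dd$feature), ,
                          drop = FALSE]
  }
  cohort$patients <- p
  cohort
}

#' Generate a cohort under the study conditions
#'
#' Convenience wrapper: [generate_base_cohort()] followed by
#' [inject_missingness()].
#'
#' @inheritParams generate_base_cohort
#' @return An `rwe_cohort`.
#' @export
generate_cohort <- function(config) {
  inject_missingness(generate_base_cohort(config))
}

#' @export
print.rwe_cohort <- function(x, ...) {
  cat("<rwe_cohort>", x$config$cancer_preset, "n =", nrow(x$patients),
      sprintf("(%.0f%% treated, %.0f%% events)\n",
              100 * mean(x$patients$treatment),
              100 * mean(x$patients$event)))
  invisible(x)
}

#' Ground-truth per-tertile treatment benefit
#'
#' Computes, from the generating model only (no estimation), the true
#' restricted-mean-survival-time difference between arms within tertiles of the
#' latent risk, using the exponential closed form per patient. With a positive
#' attenuation slope the benefit is strictly decreasing from the low- to the
#' high-risk tertile; with a homogeneous effect the three values are flagged as
#' equal-by-construction.
#'
#' @param cohort An `rwe_cohort` (pre- or post-missingness; uses ground truth).
#' @param tau RMST horizon in months.
#' @return A data.frame with columns `tertile` and `true_rmst_diff` plus
#'   attributes `homogeneous` and `decreasing`.
#' @export
planted_heterogeneity_check <- function(cohort, tau = 36) {
  stopifnot(inherits(cohort, "rwe_cohort"))
  cfg <- cohort$config
  p <- cohort$patients
  lp <- p$latent_true_risk
  loghr_eff <- effective_treatment_loghr(cfg, lp)
  r0 <- cfg$baseline_hazard * exp(lp)
  r1 <- r0 * exp(loghr_eff)
  diff_i <- exp_rmst(r1, tau) - exp_rmst(r0, tau)
  cut <- stats::quantile(lp, c(1, 2) / 3, names = FALSE)
  tert <- factor(1 + (lp > cut[1]) + (lp > cut[2]), levels = 1:3,
                 labels = c("low", "medium", "high"))
  out <- data.frame(tertile = levels(tert),
                    true_rmst_diff = as.numeric(tapply(diff_i, tert, mean)))
  attr(out, "homogeneous") <- cfg$effect_modification == 0
  attr(out, "decreasing") <- all(diff(out$true_rmst_diff) < 0)
  if (attr(out, "homogeneous")) attr(out, "decreasing") <- FALSE
  out
}

#' Write or read a cohort on disk
#'
#' Persists the wide patient table and long observation table as CSV (or as
#' Parquet columnar files when `format = "parquet"` and the `arrow` package is
#' available), together with the generating config as YAML.
#'
#' @param cohort An `rwe_cohort`.
#' @param dir Directory to create/read.
#' @param format `"csv"` or `"parquet"`.
#' @return `write_cohort` the directory, invisibly; `read_cohort` the cohort.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for parquet output")
    }
    arrow::write_parquet(cohort$patients, file.path(dir, "patients.parquet"))
    arrow::write_parquet(cohort$observations,
                         file.path(dir, "observations.parquet"))
  } else {
    utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$observations, file.path(dir, "observations.csv"),
                     row.names = FALSE)
  }
  write_cohort_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pq <- file.exists(file.path(dir, "patients.parquet"))
  patients <- if (pq) {
    as.data.frame(arrow::read_parquet(file.path(dir, "patients.parquet")))
  } else {
    utils::read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  }
  observations <- if (pq) {
    as.data.frame(arrow::read_parquet(file.path(dir, "observations.parquet")))
  } else {
    utils::read.csv(file.path(dir, "observations.csv"),
                    stringsAsFactors = FALSE)
  }
  structure(list(patients = patients, observations = observations,
                 config = read_cohort_config(file.path(dir, "config.yaml"))),
            class = "rwe_cohort")
}
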