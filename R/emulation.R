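#' Match a cohort against a trial's eligibility criteria
#'
#' `key` mode applies the core rules: correct cancer type, receipt of an arm
#' regimen at the appropriate line of therapy, and the required biomarker
#' status captured up to 30 days after treatment start. `strict` mode
#' additionally removes patients with an exclusionary comorbidity flagged in
#' the year before treatment start, an ECOG score above the cutoff (the score
#' closest to and before treatment start; unknown ECOG is retained), organ
#' dysfunction on any laboratory value in the 3 months before treatment, or an
#' exclusionary metastasis site in the 3 months before treatment.
#' `standard_dose` mode further requires a known first dose at or above the
#' specified minimum. Time zero is the start of the qualifying line of
#' therapy; all lookbacks are measured from that date.
#'
#' @param cohort An `rwe_cohort`.
#' @param trial An `rwe_trial_spec`.
#' @param mode One of `"key"`, `"strict"`, `"standard_dose"`.
#' @return List with `data` (eligible patients, arm indicator `Z`),
#'   `attrition` (per-rule exclusion counts) and `mode`.
#' @export
match_eligibility <- function(cohort, trial,
                              mode = c("key", "strict", "standard_dose")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "rwe_cohort"), inherits(trial, "rwe_trial_spec"))
  p <- cohort$patients
  obs <- cohort$observations
  rules <- list()
  keep <- rep(TRUE, nrow(p))
  note <- function(rule, drop) {
    rules[[length(rules) + 1]] <<- data.frame(
      rule = rule, excluded = sum(drop & keep),
      remaining = sum(keep) - sum(drop & keep))
    keep <<- keep & !drop
  }

  note("cancer_type", rep(cohort$config$cancer_preset != trial$cancer_preset,
                          nrow(p)))
  Z <- ifelse(p$regimen %in% trial$arms$treatment$regimens, 1L,
              ifelse(p$regimen %in% trial$arms$control$regimens, 0L,
                     NA_integer_))
  note("arm_regimen", is.na(Z))
  line_req <- ifelse(Z == 1, trial$arms$treatment$line, trial$arms$control$line)
  note("line_of_therapy", !is.na(Z) & p$line_of_therapy != line_req)

  if (!is.null(trial$biomarker)) {
    bm <- trial$biomarker
    if (!bm$column %in% names(p)) {
      stop("cohort lacks the biomarker column required by the trial spec: ",
           bm$column)
    }
    window <- bm$window_after_start %||% 30
    val_ok <- !is.na(p[[bm$column]]) & p[[bm$column]] == bm$required_value
    date_ok <- !is.na(p$biomarker_day) &
      p$biomarker_day <= p$treatment_start + window
    note("biomarker", !(val_ok & date_ok))
  }

  if (mode %in% c("strict", "standard_dose") && !is.null(trial$strict)) {
    s <- trial$strict
    for (cm in s$exclude_comorbidities %||% character(0)) {
      lb <- s$comorbidity_lookback_days %||% 365
      day <- p[[paste0(cm, "_day")]]
      drop <- !is.na(p[[cm]]) & p[[cm]] == 1 & !is.na(day) &
        day > p$treatment_start - lb & day <= p$treatment_start
      note(paste0("comorbidity_", cm), drop)
    }
    if (!is.null(s$ecog_max)) {
      ecog_pre <- lookup_closest_before(obs, "ecog", p$patient_id,
                                        p$treatment_start)
      note("ecog_cutoff", !is.na(ecog_pre) & ecog_pre > s$ecog_max)
    }
    for (lab in names(s$lab_limits %||% list())) {
      lim <- s$lab_limits[[lab]]
      lb <- s$lab_lookback_days %||% 90
      bad <- lab_violation(obs, lab, p$patient_id, p$treatment_start, lb,
                           lim$min, lim$max)
      note(paste0("lab_", lab), bad)
    }
    for (site in s$exclude_met_sites %||% character(0)) {
      flag <- paste0("met_", site); daycol <- paste0("met_", site, "_day")
      if (!flag %in% names(p)) next
      lb <- s$met_lookback_days %||% 90
      drop <- !is.na(p[[flag]]) & p[[flag]] == 1 & !is.na(p[[daycol]]) &
        p[[daycol]] > p$treatment_start - lb & p[[daycol]] <= p$treatment_start
      note(paste0("met_site_", site), drop)
    }
  }
  if (mode == "standard_dose") {
    if (is.null(trial$standard_dose)) {
      stop("trial spec has no standard_dose rule")
    }
    note("standard_dose",
         is.na(p$first_dose) | p$first_dose < trial$standard_dose$min_first_dose)
  }

  out <- p[keep, , drop = FALSE]
  out$Z <- Z[keep]
  attrition <- do.call(rbind, rules)
  attrition <- rbind(attrition,
                     data.frame(rule = "eligible", excluded = 0L,
                                remaining = nrow(out)))
  list(data = out, attrition = attrition, mode = mode)
}

# Observation value closest to, and strictly before or at, a per-patient
# reference day.
lookup_closest_before <- function(obs, feature, patient_ids, ref_days) {
  sel <- obs$feature == feature
  o <- obs[sel, , drop = FALSE]
  out <- rep(NA_real_, length(patient_ids))
  idx <- split(seq_len(nrow(o)), o$patient_id)
  pos <- match(names(idx), patient_ids)
  for (k in seq_along(idx)) {
    i <- pos[k]
    if (is.na(i)) next
    d <- o$day[idx[[k]]]; v <- o$value[idx[[k]]]
    ok <- d <= ref_days[i]
    if (!any(ok)) next
    out[i] <- v[ok][which.max(d[ok])]
  }
  out
}

lab_violation <- function(obs, lab, patient_ids, ref_days, lookback,
                          min_ok = NULL, max_ok = NULL) {
  sel <- obs$feature == lab
  o <- obs[sel, , drop = FALSE]
  out <- rep(FALSE, length(patient_ids))
  idx <- split(seq_len(nrow(o)), o$patient_id)
  pos <- match(names(idx), patient_ids)
  for (k in seq_along(idx)) {
    i <- pos[k]
    if (is.na(i)) next
    d <- o$day[idx[[k]]]; v <- o$value[idx[[k]]]
    ok <- d > ref_days[i] - lookback & d <= ref_days[i]
    if (!any(ok)) next
    v <- v[ok]
    out[i] <- (!is.null(min_ok) && any(v < min_ok)) ||
      (!is.null(max_ok) && any(v > max_ok))
  }
  out
}

#' Assign prognostic phenotypes by risk-score tertile
#'
#' Patients are labelled `low`, `medium` or `high` risk by the 1/3 and 2/3
#' empirical quantiles of the risk score; when cutpoints are supplied (the
#' holdout protocol) they are applied as-is and the provenance is recorded.
#' A score exactly at a cutpoint goes to the lower-risk group.
#'
#' @param scores Numeric risk scores (higher = higher mortality risk).
#' @param cutpoints Optional length-2 ordered cutpoints on the score scale.
#' @return An object of class `rwe_phenotypes`: list with `assignment`
#'   (factor low/medium/high), `cutpoints`, `provenance`.
#' @export
assign_phenotypes <- function(scores, cutpoints = NULL) {
  stopifnot(length(scores) >= 3, !anyNA(scores))
  provenance <- "computed"
  if (is.null(cutpoints)) {
    if (length(unique(scores)) == 1) {
      stop("all risk scores identical: tertiles do not exist")
    }
    cutpoints <- stats::quantile(scores, c(1, 2) / 3, names = FALSE)
  } else {
    stopifnot(length(cutpoints) == 2, diff(cutpoints) >= 0)
    provenance <- "supplied"
  }
  grp <- 1 + (scores > cutpoints[1]) + (scores > cutpoints[2])
  structure(list(
    assignment = factor(c("low", "medium", "high")[grp],
                        levels = c("low", "medium", "high")),
    cutpoints = as.numeric(cutpoints), provenance = provenance
  ), class = "rwe_phenotypes")
}

#' Estimate propensity scores by logistic regression
#'
#' Unpenalized logistic regression of the arm indicator on the supplied
#' covariates; the probability of assignment to the treatment arm. Perfect or
#' quasi-perfect separation raises an error advising covariate review rather
#' than silently regularizing.
#'
#' @param data A data.frame containing the covariates and the arm indicator.
#' @param covariates Character vector of covariate names (factors allowed).
#' @param treatment_col Name of the 0/1 arm column.
#' @return Numeric vector of propensities in `(0, 1)`.
#' @export
estimate_propensity <- function(data, covariates, treatment_col = "Z") {
  z <- data[[treatment_col]]
  if (length(unique(z)) < 2) stop("both arms must be present")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("propensity covariate(s) not in data: ",
         paste(missing_cov, collapse = ", "))
  }
  fml <- stats::as.formula(paste(
    treatment_col, "~",
    if (length(covariates)) paste(covariates, collapse = " + ") else "1"))
  fit <- suppressWarnings(stats::glm(fml, data = data, family = stats::binomial()))
  e <- stats::fitted(fit)
  if (!fit$converged || any(e > 1 - 1e-8) || any(e < 1e-8)) {
    stop("propensity model shows (quasi-)separation; review the covariates")
  }
  as.numeric(e)
}

#' Inverse probability of treatment weights
#'
#' \eqn{\omega_i = Z_i/e_i + (1 - Z_i)/(1 - e_i)}, exactly, with no trimming
#' or truncation. Propensities of exactly 0 or 1 are a positivity violation
#' and raise an error.
#'
#' @param e Propensities in `(0, 1)`.
#' @param Z 0/1 arm indicator.
#' @return Object of class `rwe_iptw`: list with `e`, `Z`, `weights`.
#' @export
iptw_weights <- function(e, Z) {
  stopifnot(length(e) == length(Z), all(Z %in% c(0, 1)))
  if (any(e <= 0 | e >= 1)) {
    stop("positivity violation: propensity of 0 or 1")
  }
  w <- Z / e + (1 - Z) / (1 - e)
  structure(list(e = as.numeric(e), Z = as.integer(Z), weights = as.numeric(w)),
            class = "rwe_iptw")
}

#' Standardized mean differences before and after weighting
#'
#' For each covariate (factors one-hot expanded) the between-arm difference in
#' (weighted) means divided by the pooled unweighted standard deviation,
#' reported in percent. A zero pooled SD yields an SMD of 0 with a flag.
#'
#' @param data Data.frame with covariates and arm indicator.
#' @param weights IPTW weights (numeric) or an `rwe_iptw` object.
#' @param covariates Covariate names.
#' @param treatment_col Arm column name.
#' @return Data.frame `covariate`, `smd_unweighted`, `smd_weighted`,
#'   `zero_sd` (percent scale).
#' @export
smd_table <- function(data, weights, covariates, treatment_col = "Z") {
  if (inherits(weights, "rwe_iptw")) weights <- weights$weights
  z <- data[[treatment_col]]
  mm <- stats::model.matrix(
    ~ . - 1, data = data[, covariates, drop = FALSE])
  res <- lapply(colnames(mm), function(cl) {
    x <- mm[, cl]
    s_pool <- sqrt((stats::var(x[z == 1]) + stats::var(x[z == 0])) / 2)
    zero_sd <- !is.finite(s_pool) || s_pool == 0
    raw <- mean(x[z == 1]) - mean(x[z == 0])
    wtd <- weighted_mean(x[z == 1], weights[z == 1]) -
      weighted_mean(x[z == 0], weights[z == 0])
    data.frame(covariate = cl,
               smd_unweighted = if (zero_sd) 0 else 100 * raw / s_pool,
               smd_weighted = if (zero_sd) 0 else 100 * wtd / s_pool,
               zero_sd = zero_sd)
  })
  do.call(rbind, res)
}

#' Default propensity-model covariates for the synthetic cohorts
#'
#' Demographics, year of diagnosis, ECOG, time to metastasis, histology,
#' biomarker status, albumin and weight change; the fitted mortality risk
#' score is appended by the emulation engine when available.
#'
#' @return Character vector of column names.
#' @export
default_propensity_covariates <- function() {
  c("age", "sex", "year_of_dx", "ecog", "time_to_met", "histology", "pdl1",
    "albumin", "weight_pct_change")
}
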