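#' Subset a cohort to a set of patients
#'
#' @param cohort An `rwe_cohort`.
#' @param ids Patient ids to keep.
#' @return The subset cohort.
#' @export
subset_cohort <- function(cohort, ids) {
  cohort$patients <- cohort$patients[cohort$patients$patient_id %in% ids, ,
                                     drop = FALSE]
  cohort$observations <-
    cohort$observations[cohort$observations$patient_id %in% ids, , drop = FALSE]
  cohort
}

#' Emulate a phase 3 trial in an observational cohort
#'
#' Runs the full emulation for one trial: eligibility matching, prognostic
#' phenotyping into risk tertiles, propensity estimation and inverse
#' probability of treatment weighting, balance diagnostics, weighted
#' Kaplan-Meier estimation of median survival, RMST at the benchmark-implied
#' horizon and survival probabilities with bootstrap CIs (IPTW refit inside
#' every replicate), a robust Cox hazard ratio for the full eligible cohort,
#' and the three RCT agreement criteria.
#'
#' @param cohort An `rwe_cohort`.
#' @param trial An `rwe_trial_spec`.
#' @param model Optional fitted prognostic model ([tune_and_fit()] /
#'   [fit_benchmark_cox()]); used to score patients.
#' @param risk_scores Optional named vector of risk scores (names =
#'   patient_id), overriding `model`.
#' @param features Optional imputed `rwe_features`; built from the cohort when
#'   absent (imputer fit on the full cohort).
#' @param mode Eligibility mode.
#' @param cutpoints Optional supplied tertile cutpoints (holdout protocol).
#' @param tau RMST horizon; defaults to [rmst_horizon()] of the trial.
#' @param reps Bootstrap replicates.
#' @param seed Integer seed.
#' @param propensity_covariates Covariates for the propensity model; the
#'   mortality risk score (`risk_score`) is always appended.
#' @param timepoints Optional survival-probability timepoints (months).
#' @return Object of class `rwe_emulation`.
#' @export
emulate_trial <- function(cohort, trial, model = NULL, risk_scores = NULL,
                          features = NULL, mode = "key", cutpoints = NULL,
                          tau = NULL, reps = 1000, seed = 1L,
                          propensity_covariates = default_propensity_covariates(),
                          timepoints = NULL) {
  stopifnot(inherits(cohort, "rwe_cohort"), inherits(trial, "rwe_trial_spec"))
  elig <- match_eligibility(cohort, trial, mode)
  if (nrow(elig$data) < 30) stop("fewer than 30 eligible patients")
  if (is.null(features)) {
    features <- build_feature_matrix(cohort)
    features <- impute_default(features, fit_imputer(features))
  }
  if (is.null(risk_scores)) {
    if (is.null(model)) {
      model <- fit_benchmark_cox(features)
    }
    risk_scores <- predict_risk(model, features)
    names(risk_scores) <- features$patient_id
  }
  d <- elig$data
  frow <- match(d$patient_id, features$patient_id)
  cov_df <- features[frow, , drop = FALSE]
  scores <- as.numeric(risk_scores[d$patient_id])
  phen <- assign_phenotypes(scores, cutpoints = cutpoints)
  tau <- tau %||% rmst_horizon(trial)

  adf <- data.frame(time = d$time, event = d$event, Z = d$Z,
                    risk_score = scores)
  pcov <- intersect(propensity_covariates, names(cov_df))
  adf <- cbind(adf, cov_df[, pcov, drop = FALSE])
  if ("ecog" %in% pcov) {
    # ordinal score + unknown flag: one slope instead of five dummies, which
    # keeps small-stratum bootstrap propensity fits away from separation
    ec <- as.character(adf$ecog)
    adf$ecog_unknown <- as.numeric(ec == "unknown")
    adf$ecog_score <- ifelse(ec == "unknown", 1, suppressWarnings(as.numeric(ec)))
    pcov <- c(setdiff(pcov, "ecog"), "ecog_score", "ecog_unknown")
  }
  pcov_all <- c(pcov, "risk_score")

  run_stratum <- function(rows, stratum, seed_i) {
    ds <- adf[rows, , drop = FALSE]
    e <- estimate_propensity(ds, pcov_all)
    w <- iptw_weights(e, ds$Z)
    boot <- bootstrap_effects(ds, tau, pcov_all, reps = reps,
                              seed = seed_i, timepoints = timepoints)
    hr <- tryCatch(
      cox_iptw_hr(ds$time, ds$event, ds$Z, w$weights),
      error = function(e) NULL)
    km_arm <- function(z) {
      k <- weighted_km(ds$time[ds$Z == z], ds$event[ds$Z == z],
                       w$weights[ds$Z == z])
      data.frame(stratum = stratum, arm = ifelse(z == 1, "treatment",
                                                 "control"),
                 time = k$time, surv = k$surv)
    }
    list(stratum = stratum, n = nrow(ds),
         smd = smd_table(ds, w, pcov_all),
         effective_n = sum(w$weights)^2 / sum(w$weights^2),
         km = rbind(km_arm(1), km_arm(0)),
         estimates = boot$estimates, ci = boot$ci,
         hr = hr, diagnostics = boot$diagnostics)
  }

  strata <- list(full = seq_len(nrow(adf)))
  for (lev in levels(phen$assignment)) {
    strata[[lev]] <- which(phen$assignment == lev)
  }
  results <- list()
  for (i in seq_along(strata)) {
    results[[names(strata)[i]]] <-
      run_stratum(strata[[i]], names(strata)[i], child_seed(seed, i))
  }
  agreement <- if (!is.null(results$full$hr)) {
    assess_agreement(results$full$hr,
                     list(hr = trial$benchmark$hr,
                          ci_lower = trial$benchmark$ci_lower,
                          ci_upper = trial$benchmark$ci_upper))
  } else NULL

  structure(list(
    trial_id = trial$trial_id, mode = mode, tau = tau,
    attrition = elig$attrition, phenotypes = phen,
    strata = results, hr = results$full$hr, agreement = agreement,
    seed = as.integer(seed)
  ), class = "rwe_emulation")
}

#' @export
print.rwe_emulation <- function(x, ...) {
  cat("<rwe_emulation>", x$trial_id, sprintf("[%s eligibility]", x$mode),
      "n =", x$strata$full$n, "\n")
  if (!is.null(x$hr)) {
    cat(sprintf("  HR %.3f (%.3f-%.3f), robust SE %.3f\n", x$hr$hr,
                x$hr$ci_lower, x$hr$ci_upper, x$hr$se_robust))
  }
  if (!is.null(x$agreement)) {
    cat("  agreement: significance =", x$agreement$significance,
        "| CI overlap =", x$agreement$ci_overlap,
        "| standardized difference =", x$agreement$standardized_difference,
        "\n")
  }
  for (s in c("low", "medium", "high")) {
    est <- x$strata[[s]]$estimates
    cat(sprintf("  %-6s rmst diff %.2f months (mOS %s vs %s)\n", s,
                est["rmst_diff"],
                formatC(est["mos_treatment"], digits = 3),
                formatC(est["mos_control"], digits = 3)))
  }
  invisible(x)
}

#' Holdout validation of per-phenotype treatment effects
#'
#' Splits the eligible population into halves stratified by year of metastatic
#' diagnosis and treatment receipt (half sizes within one patient per
#' stratum), refits the prognostic model on the cohort excluding the holdout
#' half, derives tertile cutpoints from the training half only, applies them
#' to both halves, and runs the emulation independently on each half.
#'
#' @param cohort An `rwe_cohort`.
#' @param trial An `rwe_trial_spec`.
#' @param seed Integer seed.
#' @param mode Eligibility mode.
#' @param reps Bootstrap replicates per half.
#' @param ... Passed to [emulate_trial()].
#' @return List with `training`, `holdout` (both `rwe_emulation`),
#'   `cutpoints`, and `agreement` (per-phenotype CI-overlap of RMST
#'   differences between halves).
#' @export
holdout_validation <- function(cohort, trial, seed = 1L, mode = "key",
                               reps = 300, ...) {
  elig <- match_eligibility(cohort, trial, mode)
  d <- elig$data
  set.seed(child_seed(seed, 7L))
  holdout <- logical(nrow(d))
  for (s in split(seq_len(nrow(d)), interaction(d$year_of_dx, d$Z,
                                                drop = TRUE))) {
    if (length(s) < 2) {
      warning("holdout stratum of size 1 assigned to training")
      next
    }
    holdout[sample(s, floor(length(s) / 2))] <- TRUE
  }
  train_ids <- d$patient_id[!holdout]
  holdout_ids <- d$patient_id[holdout]

  # prognostic model refit excluding the holdout half
  fit_cohort <- subset_cohort(cohort,
                              setdiff(cohort$patients$patient_id, holdout_ids))
  f_fit <- build_feature_matrix(fit_cohort)
  f_fit <- impute_default(f_fit, fit_imputer(f_fit))
  model <- fit_benchmark_cox(f_fit)

  f_all <- build_feature_matrix(cohort)
  f_all <- impute_default(f_all, fit_imputer(f_all, train_ids =
                                               f_fit$patient_id))
  scores <- predict_risk(model, f_all)
  names(scores) <- f_all$patient_id
  cut <- assign_phenotypes(as.numeric(scores[train_ids]))$cutpoints

  em_tr <- emulate_trial(subset_cohort(cohort, train_ids), trial,
                         risk_scores = scores, features = f_all,
                         mode = mode, cutpoints = cut, reps = reps,
                         seed = child_seed(seed, 8L), ...)
  em_ho <- emulate_trial(subset_cohort(cohort, holdout_ids), trial,
                         risk_scores = scores, features = f_all,
                         mode = mode, cutpoints = cut, reps = reps,
                         seed = child_seed(seed, 9L), ...)
  agree <- vapply(c("low", "medium", "high"), function(s) {
    ci_tr <- em_tr$strata[[s]]$ci
    ci_ho <- em_ho$strata[[s]]$ci
    tr <- ci_tr[ci_tr$estimand == "rmst_diff", ]
    ho <- ci_ho[ci_ho$estimand == "rmst_diff", ]
    # point estimate of each half inside the other's bootstrap CI
    (tr$estimate >= ho$lower && tr$estimate <= ho$upper) ||
      (ho$estimate >= tr$lower && ho$estimate <= tr$upper)
  }, logical(1))
  list(training = em_tr, holdout = em_ho, cutpoints = cut,
       agreement = agree,
       train_ids = train_ids, holdout_ids = holdout_ids,
       split = data.frame(half = c("training", "holdout"),
                          n = c(length(train_ids), length(holdout_ids))))
}
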