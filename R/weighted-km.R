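#' Weighted Kaplan-Meier estimate with survival summaries
#'
#' Weighted product-limit estimator (via [survival::survfit()]); with unit
#' weights it is the classical Kaplan-Meier. Summaries: the median is the
#' first time the survival curve drops to 0.5 or below (`NA` with a
#' `"not reached"` flag otherwise); the RMST is the area under the step curve
#' on `[0, tau]`, with a flat extension and a flag when `tau` exceeds the last
#' observed time; the survival probability at `t` reads the step function.
#'
#' @param times,events Observed months and event flags.
#' @param weights Non-negative weights (default 1).
#' @return Object of class `rwe_km`: list with step `time`/`surv` vectors and
#'   `n`.
#' @export
weighted_km <- function(times, events, weights = rep(1, length(times))) {
  stopifnot(all(weights >= 0), length(weights) == length(times))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           weights = weights)
  structure(list(time = fit$time, surv = fit$surv, n = length(times)),
            class = "rwe_km")
}

#' @rdname weighted_km
#' @param km An `rwe_km`.
#' @export
km_median <- function(km) {
  i <- which(km$surv <= 0.5)
  if (!length(i)) {
    structure(NA_real_, not_reached = TRUE)
  } else {
    structure(km$time[min(i)], not_reached = FALSE)
  }
}

#' @rdname weighted_km
#' @param tau RMST horizon in months.
#' @export
km_rmst <- function(km, tau) {
  stopifnot(tau > 0)
  tt <- c(0, km$time[km$time <= tau], tau)
  ss <- c(1, km$surv[km$time <= tau])
  rmst <- sum(ss * diff(tt))
  structure(rmst, extrapolated = tau > max(km$time))
}

#' @rdname weighted_km
#' @param t Time at which to read the survival probability.
#' @export
km_surv_prob <- function(km, t) {
  i <- which(km$time <= t)
  if (!length(i)) 1 else km$surv[max(i)]
}

#' RMST horizon implied by the RCT benchmark
#'
#' The restricted-mean horizon is the benchmark median (overall survival, or
#' progression-free survival for PFS-primary trials) plus 12 months, allowing
#' adequate time for arm separation. A benchmark whose median was not reached
#' has no implied horizon and `tau` must be user-supplied.
#'
#' @param trial An `rwe_trial_spec`.
#' @return Horizon `tau` in months.
#' @export
rmst_horizon <- function(trial) {
  b <- trial$benchmark
  endpoint <- b$endpoint %||% "OS"
  med <- if (endpoint == "PFS") {
    b$mpfs_control %||% b$mpfs_treatment
  } else {
    b$mos_control %||% b$mos_treatment
  }
  if (is.null(med) || is.na(med)) {
    stop("benchmark median not available (not reached?); supply tau explicitly")
  }
  med + 12
}

#' Hazard ratio from a weighted Cox model with robust standard errors
#'
#' Weighted Cox partial likelihood with the treatment indicator as the sole
#' covariate by default (optional additional adjustment covariates), robust
#' variance by the Huber sandwich estimator, and a Wald interval on the log
#' scale.
#'
#' @param times,events,Z Outcome and 0/1 arm indicator.
#' @param weights IPTW weights (numeric or `rwe_iptw`).
#' @param covariates Optional adjustment covariates (requires `data`).
#' @param data Data.frame holding `covariates`.
#' @param level Confidence level.
#' @return List `hr`, `log_hr`, `se_robust`, `ci_lower`, `ci_upper`, `n`,
#'   `events`.
#' @export
cox_iptw_hr <- function(times, events, Z, weights = rep(1, length(times)),
                        covariates = NULL, data = NULL, level = 0.95) {
  if (inherits(weights, "rwe_iptw")) weights <- weights$weights
  stopifnot(all(Z %in% c(0, 1)))
  if (!any(events[Z == 1] == 1) || !any(events[Z == 0] == 1)) {
    stop("each arm must have at least one event")
  }
  df <- data.frame(.time = times, .event = events, .Z = Z, .w = weights)
  rhs <- ".Z"
  if (!is.null(covariates)) {
    stopifnot(!is.null(data))
    df <- cbind(df, data[, covariates, drop = FALSE])
    rhs <- paste(c(".Z", covariates), collapse = " + ")
  }
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs)),
    data = df, weights = .w, robust = TRUE)
  co <- summary(fit)$coefficients
  log_hr <- co[".Z", "coef"]
  se <- co[".Z", "robust se"]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(hr = exp(log_hr), log_hr = log_hr, se_robust = se,
       ci_lower = exp(log_hr - zq * se), ci_upper = exp(log_hr + zq * se),
       n = length(times), events = sum(events))
}

#' Bootstrap confidence intervals for the weighted survival estimands
#'
#' Resamples patients with replacement; within every replicate the propensity
#' model is refit and the weights recomputed before the weighted Kaplan-Meier
#' estimands (per-arm median survival, per-arm RMST at `tau`, RMST difference
#' and survival probabilities at requested timepoints) are re-estimated.
#' Percentile intervals; replicate-level failures of an estimand (median not
#' reached) propagate as missing and are summarized, not imputed. Replicates
#' collapsing to a single arm are dropped and counted; more than 10% dropped
#' is an error.
#'
#' @param data Data.frame with `time`, `event`, `Z` and the propensity
#'   covariates.
#' @param tau RMST horizon in months.
#' @param propensity_covariates Covariates for the within-replicate logistic
#'   model.
#' @param reps Bootstrap replicates (default 1000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @param timepoints Optional survival-probability timepoints.
#' @return List with `estimates` (point estimates on the full data), `ci`
#'   (percentile bounds), and `diagnostics` (`iptw_refits`, `dropped`,
#'   `median_not_reached` counts).
#' @export
bootstrap_effects <- function(data, tau, propensity_covariates,
                              reps = 1000, level = 0.95, seed = 1L,
                              timepoints = NULL) {
  stopifnot(reps >= 100)
  one_pass <- function(d) {
    e <- estimate_propensity(d, propensity_covariates)
    w <- iptw_weights(e, d$Z)$weights
    km1 <- weighted_km(d$time[d$Z == 1], d$event[d$Z == 1], w[d$Z == 1])
    km0 <- weighted_km(d$time[d$Z == 0], d$event[d$Z == 0], w[d$Z == 0])
    r1 <- as.numeric(km_rmst(km1, tau)); r0 <- as.numeric(km_rmst(km0, tau))
    out <- c(mos_treatment = as.numeric(km_median(km1)),
             mos_control = as.numeric(km_median(km0)),
             rmst_treatment = r1, rmst_control = r0, rmst_diff = r1 - r0)
    for (tp in timepoints %||% numeric(0)) {
      out[paste0("surv_treatment_", tp)] <- km_surv_prob(km1, tp)
      out[paste0("surv_control_", tp)] <- km_surv_prob(km0, tp)
    }
    out
  }
  point <- one_pass(data)
  set.seed(as.integer(seed))
  n <- nrow(data)
  dropped <- 0L; refits <- 0L
  boot <- matrix(NA_real_, reps, length(point),
                 dimnames = list(NULL, names(point)))
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- data[idx, , drop = FALSE]
    if (length(unique(d$Z)) < 2) { dropped <- dropped + 1L; next }
    res <- tryCatch(one_pass(d), error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    refits <- refits + 1L
    boot[r, ] <- res
  }
  if (dropped > 0.1 * reps) {
    stop("more than 10% of bootstrap replicates were dropped")
  }
  a <- (1 - level) / 2
  ci <- t(apply(boot, 2, function(v)
    stats::quantile(v, c(a, 1 - a), na.rm = TRUE, names = FALSE)))
  colnames(ci) <- c("lower", "upper")
  list(estimates = point,
       ci = data.frame(estimand = names(point), estimate = as.numeric(point),
                       lower = ci[, 1], upper = ci[, 2], row.names = NULL),
       diagnostics = list(iptw_refits = refits, dropped = dropped,
                          median_not_reached = colSums(is.na(boot))[
                            c("mos_treatment", "mos_control")] - dropped,
                          reps = reps))
}

#' Agreement between an emulated trial and its RCT benchmark
#'
#' Three criteria: (1) statistical-significance agreement - the emulated and
#' benchmark hazard ratios and their 95% CIs lie on the same side of the null;
#' (2) CI agreement - the emulated HR falls within the benchmark CI; (3)
#' standardized-difference agreement - the absolute standardized difference of
#' the log hazard ratios is below 1.96, with the benchmark's standard error
#' recovered from its published CI as `(log U - log L) / (2 * 1.96)`.
#'
#' @param emulated List with `hr`, `ci_lower`, `ci_upper`, `se_robust` (as
#'   returned by [cox_iptw_hr()]).
#' @param benchmark List with `hr`, `ci_lower`, `ci_upper`.
#' @return List of three logicals (`significance`, `ci_overlap`,
#'   `standardized_difference`) plus the standardized difference value.
#' @export
assess_agreement <- function(emulated, benchmark) {
  side <- function(lo, hi) {
    if (hi < 1) "below" else if (lo > 1) "above" else "straddle"
  }
  s_em <- side(emulated$ci_lower, emulated$ci_upper)
  s_rct <- side(benchmark$ci_lower, benchmark$ci_upper)
  flag1 <- s_em != "straddle" && s_em == s_rct
  flag2 <- emulated$hr >= benchmark$ci_lower & emulated$hr <= benchmark$ci_upper
  se_rct <- (log(benchmark$ci_upper) - log(benchmark$ci_lower)) / (2 * 1.96)
  if (se_rct == 0) warning("benchmark CI has zero width; using SE 0")
  se_em <- emulated$se_robust %||%
    ((log(emulated$ci_upper) - log(emulated$ci_lower)) / (2 * 1.96))
  std_diff <- (log(emulated$hr) - log(benchmark$hr)) /
    sqrt(se_em^2 + se_rct^2)
  list(significance = flag1, ci_overlap = as.logical(flag2),
       standardized_difference = abs(std_diff) < 1.96,
       std_diff_value = std_diff)
}
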