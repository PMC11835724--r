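test_that("eligibility matching applies line, biomarker and strict rules", {
  co <- small_cohort()
  trial <- example_trial_spec()
  key <- match_eligibility(co, trial, mode = "key")
  p <- co$patients
  kept <- key$data
  # second-line patients are excluded under a first-line spec
  expect_true(all(kept$line_of_therapy == 1))
  expect_true(any(p$line_of_therapy == 2))
  # biomarker must be positive and resulted within 30 days of treatment start
  expect_true(all(kept$pdl1 == 1))
  expect_true(all(kept$biomarker_day <= kept$treatment_start + 30))
  # attrition accounting: exclusions plus eligible equal the input count
  att <- key$attrition
  expect_equal(sum(att$excluded) + nrow(kept), nrow(p))
  expect_equal(att$remaining[att$rule == "eligible"], nrow(kept))
})

test_that("strict mode excludes by labs, ECOG, comorbidity and metastasis site", {
  co <- small_cohort()
  trial <- example_trial_spec()
  # plant a hemoglobin of 8.5 g/dl two months before treatment for a patient
  # who is otherwise eligible under key criteria
  key <- match_eligibility(co, trial, "key")
  pid <- key$data$patient_id[1]
  ts <- key$data$treatment_start[1]
  co2 <- co
  co2$observations <- rbind(co2$observations,
                            data.frame(patient_id = pid,
                                       feature = "hemoglobin",
                                       day = ts - 60, value = 8.5))
  strict <- match_eligibility(co2, trial, "strict")
  expect_false(pid %in% strict$data$patient_id)
  att <- strict$attrition
  expect_true(att$excluded[att$rule == "lab_hemoglobin"] >= 1)
  expect_equal(sum(att$excluded) + nrow(strict$data), nrow(co2$patients))
  # strict keeps only ECOG <= cutoff or unknown, no recent CNS metastases
  expect_true(all(att$excluded[att$rule %in%
                                 c("ecog_cutoff", "met_site_cns")] >= 0))
  # standard-dose mode additionally drops unknown/low first doses
  sd <- match_eligibility(co2, trial, "standard_dose")
  expect_true(all(!is.na(sd$data$first_dose) & sd$data$first_dose >= 150))
})

test_that("a missing biomarker column is an explicit error", {
  co <- small_cohort()
  trial <- example_trial_spec()
  trial$biomarker$column <- "her2"
  expect_error(match_eligibility(co, trial), "her2")
})

test_that("phenotype tertiles split counts and honour supplied cutpoints", {
  ph <- assign_phenotypes(c(10, 20, 30, 40, 50, 60, 70, 80, 90))
  expect_equal(as.vector(table(ph$assignment)), c(3, 3, 3))
  expect_equal(ph$provenance, "computed")
  # supplied cutpoints (holdout protocol) applied as-is, unequal groups fine
  ph2 <- assign_phenotypes(c(1, 2, 3, 4, 100), cutpoints = c(40, 60))
  expect_equal(ph2$provenance, "supplied")
  expect_equal(as.vector(table(ph2$assignment)), c(4, 0, 1))
  # boundary ties go to the lower-risk group deterministically
  ph3 <- assign_phenotypes(c(1, 1, 1, 2, 3, 4))
  expect_equal(sum(ph3$assignment == "low"), 3)
  expect_error(assign_phenotypes(rep(2, 10)), "identical")
})

test_that("propensity closed forms hold for degenerate models", {
  d <- data.frame(Z = c(1, 1, 0, 0, 1, 0, 0, 0),
                  x = c(1, 1, 1, 1, 0, 0, 0, 0))
  e0 <- estimate_propensity(d, character(0))
  expect_equal(e0, rep(mean(d$Z), nrow(d)))
  e1 <- estimate_propensity(d, "x")
  expect_equal(e1[d$x == 1], rep(0.5, 4), tolerance = 1e-6)
  expect_equal(e1[d$x == 0], rep(0.25, 4), tolerance = 1e-6)
  # perfect separation errors instead of silently regularizing
  d2 <- data.frame(Z = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  expect_error(estimate_propensity(d2, "x"), "separation")
})

test_that("IPTW weights follow the closed form with no trimming", {
  w <- iptw_weights(c(0.5, 0.25, 0.25), c(1, 1, 0))
  expect_equal(w$weights, c(2, 4, 4 / 3))
  expect_true(all(w$weights >= 1))
  expect_error(iptw_weights(c(0.5, 0), c(1, 0)), "positivity")
  # expectation identity: mean weight ~ 2 under correct propensities
  set.seed(2)
  x <- rnorm(20000)
  e <- plogis(0.3 + 0.8 * x)
  z <- rbinom(20000, 1, e)
  expect_equal(mean(iptw_weights(e, z)$weights), 2, tolerance = 0.05)
})

test_that("SMDs vanish for identical arms and shrink under weighting", {
  set.seed(3)
  d <- data.frame(Z = rep(c(0, 1), each = 200), x = rep(rnorm(200), 2))
  s <- smd_table(d, rep(1, 400), "x")
  expect_equal(s$smd_unweighted, 0, tolerance = 1e-10)
  # constant covariate: zero pooled SD flagged, SMD reported as 0
  d$k <- 1
  s2 <- smd_table(d, rep(1, 400), c("x", "k"))
  expect_true(s2$zero_sd[s2$covariate == "k"])
  expect_equal(s2$smd_weighted[s2$covariate == "k"], 0)
})

test_that("weighted KM reduces to the classical estimator at unit weights", {
  d <- censored_sample(300, seed = 4)
  km <- weighted_km(d$time, d$event)
  cl <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  expect_equal(km$time, cl$time)
  expect_equal(km$surv, cl$surv)
  expect_equal(as.numeric(km_median(km)),
               unname(summary(cl)$table["median"]))
})

test_that("flat curves give RMST equal to tau and an unreached median", {
  km <- weighted_km(c(10, 12, 15), c(0, 0, 0))
  med <- km_median(km)
  expect_true(is.na(med) && attr(med, "not_reached"))
  r <- km_rmst(km, 8)
  expect_equal(as.numeric(r), 8)
  r2 <- km_rmst(km, 20)
  expect_true(attr(r2, "extrapolated"))
  expect_equal(km_surv_prob(km, 14), 1)
})

test_that("RMST horizon is the benchmark median plus twelve months", {
  trial <- example_trial_spec()
  trial$benchmark$mos_control <- 10.6
  expect_equal(rmst_horizon(trial), 22.6)
  trial$benchmark$endpoint <- "PFS"
  trial$benchmark$mpfs_control <- 6.4
  expect_equal(rmst_horizon(trial), 18.4)
  trial$benchmark$mpfs_control <- NULL
  expect_error(rmst_horizon(trial), "tau")
})

test_that("weighted Cox with unit weights equals the classical fit exactly", {
  d <- two_arm_exp(500, hr = 2, seed = 5)
  ours <- cox_iptw_hr(d$time, d$event, d$Z)
  classical <- survival::coxph(survival::Surv(time, event) ~ Z, data = d)
  expect_equal(ours$log_hr, unname(coef(classical)), tolerance = 1e-12)
  # and recovers the generating rate ratio within 3 robust SEs
  expect_lt(abs(ours$log_hr - log(2)), 3 * ours$se_robust)
  expect_error(cox_iptw_hr(c(1, 2), c(1, 0), c(1, 0)), "event")
})

test_that("weighted Cox CI covers a null effect at its nominal rate", {
  hits <- 0
  for (r in 1:100) {
    d <- two_arm_exp(200, hr = 1, seed = 700 + r)
    h <- cox_iptw_hr(d$time, d$event, d$Z)
    hits <- hits + (h$ci_lower <= 1 && 1 <= h$ci_upper)
  }
  expect_gte(hits, 89)
})

test_that("bootstrap refits IPTW inside every replicate and collapses when degenerate", {
  # degenerate: constant times per arm, only the intercept in the propensity
  d <- data.frame(time = rep(c(5, 3), c(30, 30)),
                  event = 1, Z = rep(c(1, 0), c(30, 30)))
  b <- bootstrap_effects(d, tau = 4, propensity_covariates = character(0),
                         reps = 150, seed = 2)
  expect_equal(b$diagnostics$iptw_refits + b$diagnostics$dropped, 150)
  ci <- b$ci
  expect_equal(ci$lower, ci$upper, tolerance = 1e-12)
  expect_equal(ci$estimate[ci$estimand == "mos_treatment"], 5)
})

test_that("bootstrap interval covers the true RMST difference near-nominally", {
  # randomized two-arm exponential generator: truth in closed form
  tau <- 15; lam0 <- 0.07; hr <- 0.6
  truth <- exp_rmst(lam0 * hr, tau) - exp_rmst(lam0, tau)
  set.seed(6)
  hits <- 0; outer_reps <- 100
  for (r in seq_len(outer_reps)) {
    d <- two_arm_exp(250, hr = hr, lambda0 = lam0, seed = 900 + r,
                     censor = 25)
    d$x <- rnorm(250)
    b <- bootstrap_effects(d, tau, propensity_covariates = "x", reps = 200,
                           seed = r)
    ci <- b$ci[b$ci$estimand == "rmst_diff", ]
    hits <- hits + (ci$lower <= truth && truth <= ci$upper)
  }
  expect_gte(hits / outer_reps, 0.88)
})

test_that("agreement flags follow the three published rules", {
  em <- list(hr = 0.70, ci_lower = 0.60, ci_upper = 0.80,
             se_robust = (log(0.80) - log(0.60)) / (2 * 1.96))
  bench <- list(hr = 0.65, ci_lower = 0.50, ci_upper = 0.80)
  a <- assess_agreement(em, bench)
  expect_true(a$significance && a$ci_overlap && a$standardized_difference)
  # CI crossing one fails significance agreement regardless of the estimate
  em2 <- list(hr = 0.7, ci_lower = 0.45, ci_upper = 1.05, se_robust = 0.2)
  expect_false(assess_agreement(em2, bench)$significance)
  # the standardized difference uses the 1.96 threshold on the log scale
  se_rct <- (log(0.80) - log(0.50)) / (2 * 1.96)
  expect_equal(a$std_diff_value,
               (log(0.70) - log(0.65)) / sqrt(em$se_robust^2 + se_rct^2))
})

test_that("emulation on an unconfounded cohort matches the crude contrast", {
  cfg <- cohort_config(n_patients = 8000, seed = 21,
                       treatment_logit_coefs = c("(Intercept)" = 0))
  co <- generate_base_cohort(cfg)
  p <- co$patients
  d <- data.frame(time = p$time, event = p$event, Z = p$treatment,
                  x = p$albumin)
  e <- estimate_propensity(d, "x")
  w <- iptw_weights(e, d$Z)$weights
  km1w <- weighted_km(d$time[d$Z == 1], d$event[d$Z == 1], w[d$Z == 1])
  km0w <- weighted_km(d$time[d$Z == 0], d$event[d$Z == 0], w[d$Z == 0])
  km1 <- weighted_km(d$time[d$Z == 1], d$event[d$Z == 1])
  km0 <- weighted_km(d$time[d$Z == 0], d$event[d$Z == 0])
  diff_w <- as.numeric(km_rmst(km1w, 24)) - as.numeric(km_rmst(km0w, 24))
  diff_c <- as.numeric(km_rmst(km1, 24)) - as.numeric(km_rmst(km0, 24))
  expect_lt(abs(diff_w - diff_c), 0.3)
})

test_that("tightening key to strict eligibility moves per-phenotype RMST little", {
  co <- mid_cohort()
  em_key <- .fixtures$em_key
  if (is.null(em_key)) {
    em_key <- suppressWarnings(
      emulate_trial(co, example_trial_spec(), mode = "key", reps = 120,
                    seed = 13))
    .fixtures$em_key <- em_key
  }
  em_strict <- suppressWarnings(
    emulate_trial(co, example_trial_spec(), mode = "strict", reps = 120,
                  seed = 13))
  for (s in c("low", "medium", "high")) {
    d_key <- em_key$strata[[s]]$estimates[["rmst_diff"]]
    d_strict <- em_strict$strata[[s]]$estimates[["rmst_diff"]]
    expect_lt(abs(d_key - d_strict), 3)
  }
})

test_that("trial specs round-trip through YAML and validate their benchmark", {
  spec <- example_trial_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_spec(spec, path)
  back <- read_trial_spec(path)
  expect_equal(back$benchmark$hr, spec$benchmark$hr)
  expect_equal(back$strict$lab_limits$hemoglobin$min, 9)
  bad <- unclass(spec)
  bad$benchmark$ci_lower <- 0.75  # CI no longer brackets the HR
  expect_error(do.call(trial_spec, bad), "bracket")
})

test_that("the shipped example trial spec file parses", {
  path <- system.file("extdata", "trial_synthetic_io.yaml",
                      package = "rwemulate")
  expect_true(nzchar(path))
  spec <- read_trial_spec(path)
  expect_s3_class(spec, "rwe_trial_spec")
  expect_equal(spec$cancer_preset, "aNSCLC-like")
})
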