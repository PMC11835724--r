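test_that("config validation names the offending field", {
  expect_error(cohort_config(n_patients = 0), "positive")
  expect_error(cohort_config(missing_rates = c(albumin = 1.2)), "\\[0, 1\\]")
  expect_error(cohort_config(missing_rates = c(event = 0.5)), "event")
  expect_error(
    cohort_config(treatment_logit_coefs = c(not_a_feature = 1)),
    "not_a_feature")
  expect_error(cohort_config(baseline_hazard = -1), "baseline_hazard")
})

test_that("configs round-trip losslessly through YAML and JSON", {
  cfg <- cohort_config(n_patients = 123, seed = 9,
                       treatment_logit_coefs = c(ecog = -0.3456789,
                                                 pdl1 = 1.23456789))
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_cohort_config(cfg, path)
    back <- read_cohort_config(path)
    expect_equal(back, cfg)
  }
})

test_that("identical config yields byte-identical cohorts", {
  cfg <- cohort_config(n_patients = 400, seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("intercept-only treatment model treats half the cohort", {
  cfg <- cohort_config(n_patients = 20000, seed = 3,
                       treatment_logit_coefs = c("(Intercept)" = 0))
  co <- generate_base_cohort(cfg)
  mc_se <- 0.5 / sqrt(20000)
  expect_lt(abs(mean(co$patients$treatment) - 0.5), 3 * mc_se)
})

test_that("observed unknown-ECOG fraction matches the configured rate", {
  cfg <- cohort_config(n_patients = 10000, seed = 5,
                       missing_rates = c(ecog = 0.53))
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(is.na(co$patients$ecog)) - 0.53), 0.02)
})

test_that("missingness saturates and vanishes at the rate extremes", {
  cfg0 <- cohort_config(n_patients = 300, seed = 4,
                        missing_rates = c(albumin = 0))
  co <- generate_base_cohort(cfg0)
  expect_identical(inject_missingness(co, cfg0), co)
  cfg1 <- cohort_config(n_patients = 300, seed = 4,
                        missing_rates = c(albumin = 1))
  co1 <- inject_missingness(generate_base_cohort(cfg1), cfg1)
  expect_true(all(is.na(co1$patients$albumin)))
})

test_that("MAR mechanism is recoverable from the masked indicator", {
  cfg <- cohort_config(n_patients = 20000, seed = 6,
                       missing_rates = c(albumin = 0.4))
  base <- generate_base_cohort(cfg)
  masked <- inject_missingness(base, cfg)
  preset <- cancer_preset(cfg$cancer_preset)
  d <- data.frame(
    miss = as.integer(is.na(masked$patients$albumin)),
    z_age = (base$patients$age - preset$age$mean) / preset$age$sd,
    ecog_hi = as.integer(base$patients$ecog >= 2))
  fit <- glm(miss ~ z_age + ecog_hi, data = d, family = binomial())
  # generating coefficient on ECOG >= 2 is 0.6 (odds ratio exp(0.6))
  expect_rel_close(exp(coef(fit)[["ecog_hi"]]), exp(0.6), 0.2)
})

test_that("event rate rises with administrative follow-up", {
  evr <- vapply(c(12, 24, 60), function(ct) {
    co <- generate_base_cohort(cohort_config(n_patients = 4000, seed = 8,
                                             admin_censor_time = ct))
    mean(co$patients$event)
  }, numeric(1))
  expect_true(all(diff(evr) > 0))
})

test_that("generating hazard coefficients are recovered on an uncensored mega-sample", {
  cfg <- cohort_config(n_patients = 50000, seed = 10,
                       admin_censor_time = 1e6, dropout_rate = 0,
                       missing_rates = c(ecog = 0))
  co <- generate_base_cohort(cfg)
  p <- co$patients
  X <- rwemulate:::feature_design(p, cancer_preset(cfg$cancer_preset))
  truth <- rwemulate:::default_outcome_coefs()
  d <- data.frame(time = p$time, event = p$event, Z = p$treatment,
                  X[, names(truth)])
  fit <- survival::coxph(
    as.formula(paste("survival::Surv(time, event) ~ Z +",
                     paste(names(truth), collapse = " + "))), data = d)
  for (nm in names(truth)) {
    expect_rel_close(exp(coef(fit)[[nm]]), exp(truth[[nm]]), 0.03)
  }
})

test_that("latent risk is positively rank-correlated with early death", {
  co <- mid_cohort()
  p <- co$patients
  died12 <- as.integer(p$time <= 12 & p$event == 1)
  tau <- cor(p$latent_true_risk, died12, method = "kendall")
  expect_gt(tau, 0)
})

test_that("latent truth never enters the model feature contract", {
  expect_false("latent_true_risk" %in% model_features())
  expect_false("treatment" %in% model_features())
  f <- small_features()
  expect_false("latent_true_risk" %in% attr(f, "model_features"))
  expect_error(
    tune_and_fit(f, model_spec("cox_benchmark"),
                 feature_cols = c("age", "latent_true_risk")),
    "leakage")
})

test_that("planted heterogeneity yields decreasing true benefit across tertiles", {
  cfg0 <- cohort_config(n_patients = 2000, seed = 12, effect_modification = 0)
  chk0 <- planted_heterogeneity_check(generate_base_cohort(cfg0))
  expect_true(attr(chk0, "homogeneous"))
  expect_lt(diff(range(chk0$true_rmst_diff)), 0.8)

  cfg1 <- cohort_config(n_patients = 50000, seed = 12,
                        effect_modification = 0.5)
  chk1 <- planted_heterogeneity_check(generate_base_cohort(cfg1))
  expect_false(attr(chk1, "homogeneous"))
  expect_true(attr(chk1, "decreasing"))
  expect_true(all(diff(chk1$true_rmst_diff) < 0))
})

test_that("closed-form exponential RMST matches numeric integration", {
  for (lam in c(0.02, 0.07, 0.2)) {
    num <- integrate(function(t) exp(-lam * t), 0, 36)$value
    expect_equal(exp_rmst(lam, 36), num, tolerance = 1e-8)
  }
})

test_that("cohorts round-trip through CSV on disk", {
  co <- generate_cohort(cohort_config(n_patients = 150, seed = 31))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$config, co$config)
  expect_equal(back$patients$time, co$patients$time)
  expect_equal(nrow(back$observations), nrow(co$observations))
})
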