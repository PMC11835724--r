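# small planted-signal survival frame for model checks
linear_signal_frame <- function(n, beta = 0.8, seed = 1, censor = 30) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  td <- rexp(n, 0.06 * exp(beta * x1))
  data.frame(patient_id = as.character(seq_len(n)), x1 = x1, x2 = x2,
             time = pmin(td, censor), event = as.integer(td <= censor))
}

test_that("a degenerate grid of size one still fits and reports its CV AUC", {
  d <- linear_signal_frame(500, seed = 1)
  m <- tune_and_fit(d, model_spec("pcox_ridge", grid = list(lambda = 0.05),
                                  horizon_months = 12, seed = 3),
                    feature_cols = c("x1", "x2"))
  expect_equal(nrow(m$cv_results), 1)
  expect_true(is.finite(m$cv_results$mean_auc))
})

test_that("early stopping keeps the learner count within the configured maximum", {
  f <- small_features()
  m <- suppressWarnings(
    tune_and_fit(f, model_spec("gbm", grid = list(eta = 0.1, max_depth = 2),
                               horizon_months = 12, seed = 2)))
  expect_true(m$nrounds >= 1 && m$nrounds <= 400)
})

test_that("penalized Cox recovers a planted linear signal well above chance", {
  d <- linear_signal_frame(1500, seed = 5)
  train <- d[1:1000, ]; test <- d[1001:1500, ]
  m <- tune_and_fit(train, model_spec("pcox_ridge", horizon_months = 12,
                                      seed = 4),
                    feature_cols = c("x1", "x2"))
  auc <- td_auc(test$time, test$event, predict_risk(m, test), 12)
  w <- censoring_weights(test$time, test$event, 12)
  n1 <- sum(w$is_case); n0 <- sum(w$is_control)
  # Hanley-McNeil standard error at the null
  se0 <- sqrt(0.25 * (1 + (n1 - 1) / 2 + (n0 - 1) / 2) / (n1 * n0))
  expect_gt(auc, 0.5 + 5 * se0)
})

test_that("risk prediction is deterministic and linear for penalized Cox", {
  d <- linear_signal_frame(800, seed = 6)
  m <- tune_and_fit(d, model_spec("pcox_ridge", grid = list(lambda = 1e-5),
                                  horizon_months = 12, seed = 1),
                    feature_cols = c("x1", "x2"))
  s1 <- predict_risk(m, d); s2 <- predict_risk(m, d)
  expect_identical(s1, s2)
  # score differences equal beta-hat times the standardized feature deltas
  beta <- as.numeric(coef(m$fit$fit, s = m$fit$s))
  X <- rwemulate:::apply_encoder(m$encoder, d)
  expect_equal(s1 - s1[1], as.numeric((X - rep(X[1, ], each = nrow(X))) %*%
                                        beta), tolerance = 1e-10)
})

test_that("scores order the true risk tertiles correctly", {
  d <- linear_signal_frame(1200, seed = 7)
  m <- tune_and_fit(d, model_spec("pcox_ridge", horizon_months = 12,
                                  seed = 2),
                    feature_cols = c("x1", "x2"))
  sc <- predict_risk(m, d)
  true_tert <- cut(d$x1, quantile(d$x1, c(0, 1 / 3, 2 / 3, 1)),
                   include.lowest = TRUE, labels = c("lo", "mid", "hi"))
  expect_gt(mean(sc[true_tert == "hi"]), mean(sc[true_tert == "lo"]))
})

test_that("benchmark Cox recovers a rate ratio of two on exponential arms", {
  d <- two_arm_exp(3000, hr = 2, seed = 8)
  d$patient_id <- as.character(seq_len(nrow(d)))
  d$x <- d$Z
  m <- fit_benchmark_cox(d, covariates = "x")
  fit <- m$fit$fit
  se <- sqrt(diag(vcov(fit)))[["x"]]
  # the encoder standardizes x, so the fitted coefficient is log(2) * sd(x)
  s <- m$encoder$numeric$x$scale
  expect_lt(abs(coef(fit)[["x"]] - log(2) * s), 3 * se)
})

test_that("trees beat the linear benchmark when the signal is an interaction", {
  set.seed(9)
  n <- 2500
  x1 <- rnorm(n); x2 <- rnorm(n)
  td <- rexp(n, 0.06 * exp(1.2 * x1 * x2))
  d <- data.frame(patient_id = as.character(1:n), x1 = x1, x2 = x2,
                  time = pmin(td, 30), event = as.integer(td <= 30))
  train <- d[1:1700, ]; test <- d[1701:n, ]
  bench <- fit_benchmark_cox(train, covariates = c("x1", "x2"))
  gbm <- suppressWarnings(
    tune_and_fit(train, model_spec("gbm", grid = list(eta = 0.1,
                                                      max_depth = 3),
                                   horizon_months = 12, seed = 3),
                 feature_cols = c("x1", "x2")))
  auc_b <- td_auc(test$time, test$event,
                  suppressWarnings(predict_risk(bench, test)), 12)
  auc_g <- td_auc(test$time, test$event, predict_risk(gbm, test), 12)
  expect_lte(auc_b, auc_g)
})

test_that("a null covariate's Wald interval covers zero at its nominal rate", {
  hits <- 0
  for (r in 1:100) {
    d <- two_arm_exp(150, hr = 1, seed = 300 + r)
    x <- rnorm(150)
    fit <- survival::coxph(survival::Surv(d$time, d$event) ~ x)
    se <- sqrt(diag(vcov(fit)))
    hits <- hits + (abs(coef(fit)) < 1.96 * se)
  }
  expect_gte(hits, 90)
})

test_that("tree-ensemble AUC is invariant to monotone feature transforms", {
  d <- linear_signal_frame(700, seed = 10)
  spec <- model_spec("gbm", grid = list(eta = 0.1, max_depth = 2),
                     horizon_months = 12, seed = 5, early_stopping = FALSE)
  m1 <- suppressWarnings(tune_and_fit(d, spec, feature_cols = c("x1", "x2")))
  d2 <- d; d2$x1 <- exp(d$x1); d2$x2 <- d$x2^3
  m2 <- suppressWarnings(tune_and_fit(d2, spec, feature_cols = c("x1", "x2")))
  a1 <- td_auc(d$time, d$event, predict_risk(m1, d), 12)
  a2 <- td_auc(d2$time, d2$event, predict_risk(m2, d2), 12)
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("near-unpenalized Cox recovers generating coefficients at scale", {
  set.seed(11)
  n <- 20000
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rbinom(n, 1, 0.4)
  td <- rexp(n, 0.05 * exp(0.5 * x1 - 0.3 * x2 + 0.4 * x3))
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  fit <- glmnet::glmnet(X, survival::Surv(pmin(td, 40),
                                          as.integer(td <= 40)),
                        family = "cox", alpha = 0,
                        lambda = c(0.1, 0.001, 1e-5))
  b <- as.numeric(coef(fit, s = 1e-5))
  truth <- c(0.5, -0.3, 0.4)
  expect_true(all(abs(b - truth) / abs(truth) < 0.10))
})

test_that("CV fold assignment and selection are reproducible under a seed", {
  d <- linear_signal_frame(600, seed = 12)
  spec <- model_spec("pcox_lasso", horizon_months = 12, seed = 42)
  m1 <- tune_and_fit(d, spec, feature_cols = c("x1", "x2"))
  m2 <- tune_and_fit(d, spec, feature_cols = c("x1", "x2"))
  expect_identical(m1$cv_results, m2$cv_results)
  expect_identical(m1$chosen, m2$chosen)
})

test_that("unseen factor levels map to the reference with a warning", {
  f <- small_features()
  m <- fit_benchmark_cox(f)
  nd <- f[1:5, ]
  nd$histology <- c("adeno", "squamous", "other", "new_subtype", "adeno")
  expect_warning(sc <- predict_risk(m, nd), "new_subtype")
  expect_true(all(is.finite(sc)))
})

test_that("models persist to disk with JSON metadata and reload", {
  d <- linear_signal_frame(400, seed = 13)
  m <- tune_and_fit(d, model_spec("pcox_ridge", grid = list(lambda = 0.05),
                                  horizon_months = 12, seed = 1),
                    feature_cols = c("x1", "x2"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$family, "pcox_ridge")
  m2 <- load_model(path)
  expect_equal(predict_risk(m2, d), predict_risk(m, d))
})
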