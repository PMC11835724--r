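# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_cohort <- function() {
  cached("small_cohort",
         generate_cohort(cohort_config(n_patients = 1500, seed = 101)))
}

small_features <- function() {
  cached("small_features", {
    f <- build_feature_matrix(small_cohort())
    impute_default(f, fit_imputer(f))
  })
}

# mid-size cohort for estimator checks
mid_cohort <- function() {
  cached("mid_cohort",
         generate_cohort(cohort_config(n_patients = 6000, seed = 202)))
}

# base cohort + fitted DGP for the simulation audit
audit_dgp <- function() {
  cached("audit_dgp", {
    co <- generate_cohort(cohort_config(n_patients = 30000, seed = 42))
    fit_dgp(co)
  })
}

# the audit's case-1 run at study scale, shared by the bias and coverage checks
audit_case1 <- function() {
  cached("audit_case1",
         run_cases(audit_dgp(), cases = 1, sizes = 5000, reps = 500,
                   seed = 1))
}

# simple exponential two-arm survival data with known rate ratio
two_arm_exp <- function(n, hr = 2, lambda0 = 0.1, seed = 1,
                        censor = Inf) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  t_death <- rexp(n, lambda0 * hr^z)
  time <- pmin(t_death, censor)
  data.frame(time = time, event = as.integer(t_death <= censor), Z = z)
}

# survival sample with independent exponential censoring
censored_sample <- function(n, seed, lambda = 0.08, cens = 0.05,
                            beta = 0.8) {
  set.seed(seed)
  x <- rnorm(n)
  t_death <- rexp(n, lambda * exp(beta * x))
  t_cens <- if (cens > 0) rexp(n, cens) else rep(Inf, n)
  data.frame(time = pmin(t_death, t_cens),
             event = as.integer(t_death <= t_cens),
             score = x)
}

expect_rel_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
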