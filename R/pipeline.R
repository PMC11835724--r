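#' Run the two-step workflow end to end
#'
#' Step I: build the feature matrix, split train/test stratified by year of
#' diagnosis, tune the requested model families, and evaluate each family's
#' horizon AUC on the test set; the family with the highest test-set horizon
#' AUC is selected. Step II: emulate each trial across prognostic phenotypes
#' with the selected model. All artifacts are written under `out_dir`
#' together with a run manifest (seed, config hash, package version, paths).
#'
#' @param config List (or YAML/JSON path) with elements `cohort` (an
#'   `rwe_cohort` or a directory for [read_cohort()]), `trials` (list of
#'   `rwe_trial_spec` or spec file paths), and optionally `families`,
#'   `horizon_months`, `reps`, `seed`.
#' @param out_dir Output directory.
#' @return List with `model_comparison`, `selected_family`, `emulations`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("rwe_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cohort <- config$cohort
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  trials <- lapply(config$trials, function(tr) {
    if (is.character(tr)) read_trial_spec(tr) else tr
  })
  families <- config$families %||% c("pcox_ridge", "gbm", "cox_benchmark")
  seed <- as.integer(config$seed %||% 1L)
  reps <- config$reps %||% 200
  horizon <- config$horizon_months %||%
    cancer_preset(cohort$config$cancer_preset)$horizon_months
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  feats <- stage("features", {
    f <- build_feature_matrix(cohort)
    split <- split_train_test(f, seed = child_seed(seed, 1))
    train_ids <- names(split$assignment)[split$assignment == "train"]
    imp <- fit_imputer(f, train_ids)
    list(matrix = impute_default(f, imp), split = split, imputer = imp)
  })
  is_train <- feats$split$assignment == "train"
  train <- feats$matrix[is_train, , drop = FALSE]
  test <- feats$matrix[!is_train, , drop = FALSE]
  attr(train, "model_features") <- attr(feats$matrix, "model_features")

  models <- stage("train", {
    lapply(families, function(fam) {
      tune_and_fit(train, model_spec(fam, horizon_months = horizon,
                                     seed = child_seed(seed, 2)))
    })
  })
  names(models) <- families
  comparison <- stage("evaluate-auc", {
    data.frame(
      family = families,
      test_auc = vapply(models, function(m) {
        td_auc(test$time, test$event, predict_risk(m, test), horizon)
      }, numeric(1)))
  })
  selected <- comparison$family[which.max(comparison$test_auc)]
  model <- models[[selected]]

  emulations <- stage("emulate", {
    lapply(trials, function(tr) {
      emulate_trial(cohort, tr, model = model, features = feats$matrix,
                    reps = reps, seed = child_seed(seed, 3))
    })
  })
  names(emulations) <- vapply(trials, function(tr) tr$trial_id, character(1))

  utils::write.csv(comparison, file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  for (id in names(emulations)) {
    tabs <- render_report(emulations[[id]])
    utils::write.csv(tabs$estimates,
                     file.path(out_dir, paste0(id, "_estimates.csv")),
                     row.names = FALSE)
    utils::write.csv(tabs$attrition,
                     file.path(out_dir, paste0(id, "_attrition.csv")),
                     row.names = FALSE)
    km <- do.call(rbind, lapply(emulations[[id]]$strata, `[[`, "km"))
    utils::write.csv(km, file.path(out_dir, paste0(id, "_km_curves.csv")),
                     row.names = FALSE)
  }
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(list(families = families, seed = seed, reps = reps,
                            horizon = horizon,
                            cohort_config = config_as_list(cohort$config)),
                       cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(command = "run_pipeline",
                   package_version = as.character(utils::packageVersion("rwemulate")),
                   config_hash = unname(tools::md5sum(cfg_file)),
                   seed = seed,
                   families = families, selected_family = selected,
                   trials = names(emulations),
                   out_dir = out_dir,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(model_comparison = comparison, selected_family = selected,
       models = models, emulations = emulations, manifest = manifest)
}

#' Render publication-style result tables
#'
#' Produces tidy tables from an emulation result: one row per stratum with
#' per-arm median survival (explicit `"not reached"` markers), the
#' between-arm difference in medians (Delta arms = treatment minus control),
#' RMST difference with bootstrap CI, and the agreement flags. Partial
#' results render the available sections and list the gaps.
#'
#' @param result An `rwe_emulation`.
#' @return List with `estimates`, `attrition`, `agreement`, `gaps`.
#' @export
render_report <- function(result) {
  stopifnot(inherits(result, "rwe_emulation"))
  fmt_med <- function(x) ifelse(is.na(x), "not reached",
                                formatC(x, digits = 2, format = "f"))
  rows <- list(); gaps <- character(0)
  for (s in names(result$strata)) {
    st <- result$strata[[s]]
    if (is.null(st) || is.null(st$estimates)) {
      gaps <- c(gaps, s)
      rows[[s]] <- data.frame(stratum = s, n = NA_integer_,
                              mos_treatment = NA_character_,
                              mos_control = NA_character_,
                              delta_arms = NA_real_, rmst_diff = NA_real_,
                              rmst_diff_lower = NA_real_,
                              rmst_diff_upper = NA_real_)
      next
    }
    est <- st$estimates
    ci <- st$ci
    rd <- ci[ci$estimand == "rmst_diff", ]
    rows[[s]] <- data.frame(
      stratum = s, n = st$n,
      mos_treatment = fmt_med(est[["mos_treatment"]]),
      mos_control = fmt_med(est[["mos_control"]]),
      delta_arms = est[["mos_treatment"]] - est[["mos_control"]],
      rmst_diff = est[["rmst_diff"]],
      rmst_diff_lower = rd$lower, rmst_diff_upper = rd$upper)
  }
  agreement <- if (!is.null(result$agreement)) {
    data.frame(criterion = c("significance", "ci_overlap",
                             "standardized_difference"),
               agrees = c(result$agreement$significance,
                          result$agreement$ci_overlap,
                          result$agreement$standardized_difference))
  } else {
    gaps <- c(gaps, "agreement")
    NULL
  }
  list(estimates = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       attrition = result$attrition, agreement = agreement, gaps = gaps)
}

#' Emit the four cancer-preset fixture cohorts
#'
#' Writes small cohorts (one per preset) for tests and examples.
#'
#' @param dir Output directory.
#' @param n Patients per preset.
#' @param seed Integer seed.
#' @return Paths of the written cohort directories.
#' @export
write_fixture_cohorts <- function(dir, n = 2000, seed = 1L) {
  presets <- c("aNSCLC-like", "mBC-like", "mPC-like", "mCRC-like")
  paths <- character(0)
  for (i in seq_along(presets)) {
    cfg <- cohort_config(n_patients = n, cancer_preset = presets[i],
                         seed = child_seed(seed, i))
    cohort <- generate_cohort(cfg)
    path <- file.path(dir, gsub("-like", "", presets[i], fixed = TRUE))
    write_cohort(cohort, path)
    paths <- c(paths, path)
  }
  paths
}
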