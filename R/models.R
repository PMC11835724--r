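#' Specification of a prognostic survival model
#'
#' @param family One of `"gbm"` (gradient-boosted Cox-loss ensemble), `"rsf"`
#'   (random survival forest), `"ssvm"` (linear survival SVM), `"pcox_ridge"`,
#'   `"pcox_lasso"`, `"pcox_elastic"` (penalized Cox) or `"cox_benchmark"`.
#' @param grid Named list of hyperparameter candidate vectors; defaults to a
#'   small desk-scale grid per family, fully overridable.
#' @param horizon_months AUC optimization horizon: 12 for the aNSCLC-like
#'   preset, 24 for the others.
#' @param cv_folds Cross-validation folds (default 5).
#' @param early_stopping Use early stopping to fix the learner count before
#'   the grid search (ensembles only).
#' @param seed Integer seed (fold assignment and stochastic learners).
#' @return Object of class `rwe_model_spec`.
#' @export
model_spec <- function(family = c("gbm", "rsf", "ssvm", "pcox_ridge",
                                  "pcox_lasso", "pcox_elastic",
                                  "cox_benchmark"),
                       grid = NULL, horizon_months = 12, cv_folds = 5,
                       early_stopping = TRUE, seed = 1L) {
  family <- match.arg(family)
  grid <- grid %||% default_grid(family)
  if (!length(grid)) grid <- list(.dummy = 1)
  structure(list(family = family, grid = grid,
                 horizon_months = horizon_months, cv_folds = cv_folds,
                 early_stopping = isTRUE(early_stopping),
                 seed = as.integer(seed)),
            class = "rwe_model_spec")
}

default_grid <- function(family) {
  switch(family,
    gbm = list(eta = c(0.05, 0.1), max_depth = c(2, 3)),
    rsf = list(mtry_frac = c(0.33, 0.6), min_node_size = c(15)),
    ssvm = list(lambda = c(0.1, 1)),
    pcox_ridge = list(lambda = c(0.01, 0.1, 1)),
    pcox_lasso = list(lambda = c(0.005, 0.02, 0.1)),
    pcox_elastic = list(lambda = c(0.005, 0.02, 0.1)),
    cox_benchmark = list()
  )
}

# --- encoding: one-hot + median-impute + standardize, fit within folds ------

fit_encoder <- function(df, cols) {
  enc <- list(cols = cols, numeric = list(), factor = list())
  for (cl in cols) {
    v <- df[[cl]]
    if (is.numeric(v)) {
      med <- stats::median(v, na.rm = TRUE)
      v[is.na(v)] <- med
      s <- stats::sd(v)
      enc$numeric[[cl]] <- list(median = med, center = mean(v),
                                scale = if (is.na(s) || s == 0) 1 else s)
    } else {
      lev <- levels(factor(v))
      enc$factor[[cl]] <- lev
    }
  }
  enc
}

apply_encoder <- function(enc, df, warn_unseen = TRUE) {
  out <- list()
  for (cl in enc$cols) {
    v <- df[[cl]]
    if (!is.null(enc$numeric[[cl]])) {
      p <- enc$numeric[[cl]]
      v[is.na(v)] <- p$median
      out[[cl]] <- (v - p$center) / p$scale
    } else {
      lev <- enc$factor[[cl]]
      v <- as.character(v)
      unseen <- !is.na(v) & !v %in% lev
      if (any(unseen)) {
        if (warn_unseen) {
          warning("unseen level(s) in '", cl, "' mapped to reference: ",
                  paste(unique(v[unseen]), collapse = ", "))
        }
        v[unseen] <- lev[1]
      }
      v[is.na(v)] <- lev[1]
      for (l in lev[-1]) out[[paste0(cl, "_", l)]] <- as.numeric(v == l)
    }
  }
  m <- do.call(cbind, out)
  rownames(m) <- NULL
  m
}

# --- family backends --------------------------------------------------------

fit_family <- function(family, X, time, event, params, seed, nrounds = NULL) {
  set.seed(seed)
  if (family == "gbm") {
    dm <- xgboost::xgb.DMatrix(X, label = ifelse(event == 1, time, -time))
    booster <- xgboost::xgb.train(
      params = list(objective = "survival:cox", eta = params$eta,
                    max_depth = params$max_depth, subsample = 0.8,
                    nthread = 1),
      data = dm, nrounds = nrounds %||% 150, verbose = 0)
    list(kind = "gbm", booster = booster)
  } else if (family == "rsf") {
    df <- data.frame(time = time, event = event, X)
    fit <- ranger::ranger(
      survival::Surv(time, event) ~ ., data = df,
      num.trees = params$num_trees %||% 200,
      mtry = max(1, floor((params$mtry_frac %||% 0.33) * ncol(X))),
      min.node.size = params$min_node_size %||% 15,
      seed = seed, num.threads = 1, verbose = FALSE)
    list(kind = "rsf", forest = fit)
  } else if (family == "ssvm") {
    list(kind = "ssvm",
         beta = fit_ssvm_beta(X, time, event, params$lambda, seed))
  } else if (family %in% c("pcox_ridge", "pcox_lasso", "pcox_elastic")) {
    alpha <- c(pcox_ridge = 0, pcox_lasso = 1, pcox_elastic = 0.5)[[family]]
    y <- survival::Surv(time, event)
    fit <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                          lambda = sort(unique(c(params$lambda * c(10, 3, 1))),
                                        decreasing = TRUE))
    list(kind = "glmnet", fit = fit, s = params$lambda)
  } else if (family == "cox_benchmark") {
    df <- data.frame(time = time, event = event, X)
    fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df)
    if (anyNA(stats::coef(fit))) {
      stop("singular design in benchmark Cox; collinear columns: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    }
    list(kind = "coxph", fit = fit)
  } else stop("unknown family: ", family)
}

predict_family <- function(fitobj, X, horizon = 12) {
  switch(fitobj$kind,
    gbm = as.numeric(predict(fitobj$booster, xgboost::xgb.DMatrix(X),
                             outputmargin = TRUE)),
    rsf = {
      pr <- predict(fitobj$forest, data = data.frame(X), num.threads = 1)
      tp <- pr$unique.death.times
      k <- findInterval(horizon, tp)
      chf <- pr$chf
      if (k < 1) as.numeric(chf[, 1]) else as.numeric(chf[, k])
    },
    ssvm = as.numeric(X %*% fitobj$beta),
    glmnet = as.numeric(predict(fitobj$fit, newx = X, s = fitobj$s,
                                type = "link")),
    coxph = as.numeric(predict(fitobj$fit, newdata = data.frame(X),
                               type = "lp"))
  )
}

# Linear ranking SVM on comparable pairs (earlier event should score higher);
# squared hinge loss with L2 penalty, BFGS with analytic gradient.
fit_ssvm_beta <- function(X, time, event, lambda, seed, max_pairs = 40000) {
  idx_e <- which(event == 1)
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (i in idx_e) {
    j <- which(time > time[i])
    pairs_i <- c(pairs_i, rep(i, length(j))); pairs_j <- c(pairs_j, j)
  }
  if (!length(pairs_i)) stop("no comparable pairs for ssvm")
  if (length(pairs_i) > max_pairs) {
    set.seed(seed)
    k <- sample.int(length(pairs_i), max_pairs)
    pairs_i <- pairs_i[k]; pairs_j <- pairs_j[k]
  }
  np <- length(pairs_i)
  obj <- function(b) {
    s <- X %*% b
    m <- 1 - (s[pairs_i] - s[pairs_j])
    act <- m > 0
    mean(pmax(m, 0)^2) + lambda * sum(b^2)
  }
  grad <- function(b) {
    s <- X %*% b
    m <- 1 - (s[pairs_i] - s[pairs_j])
    act <- which(m > 0)
    g <- numeric(ncol(X))
    if (length(act)) {
      coefs <- -2 * m[act] / np
      Xi <- X[pairs_i[act], , drop = FALSE]
      Xj <- X[pairs_j[act], , drop = FALSE]
      g <- drop(crossprod(Xi, coefs)) - drop(crossprod(Xj, coefs))
    }
    g + 2 * lambda * b
  }
  res <- stats::optim(numeric(ncol(X)), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  beta <- res$par
  names(beta) <- colnames(X)
  beta
}

# --- tuning harness ---------------------------------------------------------

event_stratified_folds <- function(event, k, seed) {
  set.seed(seed)
  fold <- integer(length(event))
  for (grp in list(which(event == 1), which(event == 0))) {
    fold[grp] <- sample(rep_len(seq_len(k), length(grp)))
  }
  fold
}

#' Tune and fit a prognostic survival model
#'
#' Grid search with event-stratified k-fold cross-validation on the training
#' set, selecting the grid point maximizing the mean fold cumulative/dynamic
#' AUC at the model's horizon. One-hot encoding, median imputation and
#' standardization are fit within each fold. For the gradient-boosted
#' ensemble the learner count is fixed first by early stopping on an 80/20
#' validation split of the training partition (Cox partial-likelihood
#' criterion), then the remaining grid is searched. The final model is refit
#' on the full training set with the selected settings; the score orientation
#' (higher = higher mortality risk) is verified on the training data and
#' scores are negated, with a flag, if the training AUC is below 0.5.
#'
#' @param train An imputed or raw `rwe_features` data.frame (encoding imputes
#'   within folds as well).
#' @param spec An [model_spec()].
#' @param feature_cols Feature columns; defaults to the matrix's
#'   `model_features` attribute - the leakage contract - so ground-truth and
#'   treatment columns cannot enter.
#' @return Object of class `rwe_model`.
#' @export
tune_and_fit <- function(train, spec, feature_cols = NULL) {
  stopifnot(inherits(spec, "rwe_model_spec"))
  feature_cols <- feature_cols %||% attr(train, "model_features") %||%
    setdiff(names(train), c("patient_id", "time", "event", "treatment",
                            "latent_true_risk"))
  banned <- intersect(feature_cols,
                      c("latent_true_risk", "treatment", "time", "event"))
  if (length(banned)) {
    stop("feature list violates the leakage contract: ",
         paste(banned, collapse = ", "))
  }
  time <- train$time; event <- train$event
  if (sum(event) < spec$cv_folds) stop("need at least one event per fold")

  constant <- vapply(feature_cols, function(cl) {
    v <- train[[cl]]
    length(unique(v[!is.na(v)])) <= 1
  }, logical(1))
  if (any(constant)) {
    warning("dropping all-constant feature(s): ",
            paste(feature_cols[constant], collapse = ", "))
    feature_cols <- feature_cols[!constant]
  }

  nrounds <- NULL
  if (spec$family == "gbm" && spec$early_stopping) {
    nrounds <- gbm_early_stop(train, feature_cols, spec)
  }

  grid <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  fold <- event_stratified_folds(event, spec$cv_folds, spec$seed)
  cv <- data.frame(grid, mean_auc = NA_real_)
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    aucs <- vapply(seq_len(spec$cv_folds), function(k) {
      tr <- fold != k; te <- !tr
      enc <- fit_encoder(train[tr, , drop = FALSE], feature_cols)
      Xtr <- apply_encoder(enc, train[tr, , drop = FALSE], warn_unseen = FALSE)
      Xte <- apply_encoder(enc, train[te, , drop = FALSE], warn_unseen = FALSE)
      f <- fit_family(spec$family, Xtr, time[tr], event[tr], params,
                      seed = child_seed(spec$seed, 100 + k), nrounds = nrounds)
      sc <- predict_family(f, Xte, spec$horizon_months)
      tryCatch(td_auc(time[te], event[te], sc, spec$horizon_months),
               error = function(e) NA_real_)
    }, numeric(1))
    cv$mean_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv$mean_auc)
  params <- as.list(grid[best, , drop = FALSE])

  enc <- fit_encoder(train, feature_cols)
  X <- apply_encoder(enc, train, warn_unseen = FALSE)
  fitobj <- fit_family(spec$family, X, time, event, params,
                       seed = child_seed(spec$seed, 999), nrounds = nrounds)
  sc <- predict_family(fitobj, X, spec$horizon_months)
  train_auc <- tryCatch(td_auc(time, event, sc, spec$horizon_months),
                        error = function(e) NA_real_)
  flipped <- isTRUE(!is.na(train_auc) && train_auc < 0.5)
  if (flipped) {
    warning("score orientation flipped: training AUC below 0.5")
  }
  structure(list(family = spec$family, fit = fitobj, encoder = enc,
                 feature_cols = feature_cols, chosen = params,
                 nrounds = nrounds, cv_results = cv,
                 horizon_months = spec$horizon_months,
                 train_auc = if (flipped) 1 - train_auc else train_auc,
                 flipped = flipped, seed = spec$seed),
            class = "rwe_model")
}

gbm_early_stop <- function(train, feature_cols, spec, max_rounds = 400,
                           patience = 25) {
  set.seed(child_seed(spec$seed, 55))
  n <- nrow(train)
  val <- sample.int(n, max(1, floor(0.2 * n)))
  tr <- setdiff(seq_len(n), val)
  enc <- fit_encoder(train[tr, , drop = FALSE], feature_cols)
  Xtr <- apply_encoder(enc, train[tr, , drop = FALSE], warn_unseen = FALSE)
  Xva <- apply_encoder(enc, train[val, , drop = FALSE], warn_unseen = FALSE)
  lab <- function(i) ifelse(train$event[i] == 1, train$time[i],
                            -train$time[i])
  dtr <- xgboost::xgb.DMatrix(Xtr, label = lab(tr))
  dva <- xgboost::xgb.DMatrix(Xva, label = lab(val))
  booster <- xgboost::xgb.train(
    params = list(objective = "survival:cox", eta = 0.1, max_depth = 3,
                  subsample = 0.8, nthread = 1),
    data = dtr, nrounds = max_rounds, evals = list(val = dva),
    early_stopping_rounds = patience, verbose = 0)
  best <- xgboost::xgb.attr(booster, "best_iteration")
  n_best <- suppressWarnings(as.integer(best))
  if (is.na(n_best) || n_best < 1) n_best <- max_rounds
  min(n_best, max_rounds)
}

#' Predict mortality risk scores
#'
#' Deterministic given the fitted state; one finite score per row, higher =
#' greater mortality risk. Unseen categorical levels are mapped to the
#' encoding's reference level with a warning.
#'
#' @param model An `rwe_model`.
#' @param newdata Feature data.frame containing the model's feature columns.
#' @return Numeric risk scores.
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "rwe_model"))
  missing_cols <- setdiff(model$feature_cols, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks model feature(s): ",
         paste(missing_cols, collapse = ", "))
  }
  X <- apply_encoder(model$encoder, newdata)
  sc <- predict_family(model$fit, X, model$horizon_months)
  if (model$flipped) sc <- -sc
  sc
}

#' Unpenalized benchmark Cox model
#'
#' Standard partial-likelihood fit on a published-style covariate list; the
#' same score-orientation contract as the ML families. A singular design is
#' an error listing the collinear columns.
#'
#' @param train Imputed `rwe_features`.
#' @param covariates Covariate list (subset of available features).
#' @param horizon_months Horizon used when the model is evaluated.
#' @return An `rwe_model` of family `cox_benchmark`.
#' @export
fit_benchmark_cox <- function(train,
                              covariates = c("age", "sex", "ecog", "albumin",
                                             "hemoglobin", "weight_pct_change",
                                             "smoker", "histology",
                                             "time_to_met"),
                              horizon_months = 12) {
  missing_cov <- setdiff(covariates, names(train))
  if (length(missing_cov)) {
    stop("covariate(s) not in training data: ",
         paste(missing_cov, collapse = ", "))
  }
  spec <- model_spec("cox_benchmark", horizon_months = horizon_months,
                     early_stopping = FALSE)
  tune_and_fit(train, spec, feature_cols = covariates)
}

#' @export
print.rwe_model <- function(x, ...) {
  cat("<rwe_model>", x$family, "| horizon", x$horizon_months, "months",
      "| CV AUC", formatC(max(x$cv_results$mean_auc, na.rm = TRUE),
                          digits = 3, format = "f"), "\n")
  invisible(x)
}

#' Persist or restore a fitted model
#'
#' The fitted state goes to a versioned binary file with a JSON metadata
#' sidecar (family, features, chosen hyperparameters, CV AUCs).
#'
#' @param model An `rwe_model`.
#' @param path Path of the binary file; metadata goes to `<path>.json`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(format_version = 1L, family = model$family,
               features = model$feature_cols, chosen = model$chosen,
               horizon_months = model$horizon_months,
               cv = model$cv_results, flipped = model$flipped)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "rwe_model"))
  m
}
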