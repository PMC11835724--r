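#' Select the observation closest to the index date
#'
#' Data-collection window from 90 days before to 30 days after the index date;
#' the in-window value whose date is closest to the index is returned, with a
#' tie between a pre- and post-index observation resolved in favour of the
#' pre-index one (pre-treatment information preferred). An empty window yields
#' `NA`.
#'
#' @param days Integer days relative to the index date.
#' @param values Observation values.
#' @param window Length-2 window in days, default `c(-90, 30)`.
#' @return A single value or `NA`.
#' @export
select_index_window <- function(days, values, window = c(-90, 30)) {
  stopifnot(length(days) == length(values))
  keep <- !is.na(days) & days >= window[1] & days <= window[2]
  if (!any(keep)) return(NA_real_)
  days <- days[keep]; values <- values[keep]
  d <- abs(days)
  cand <- which(d == min(d))
  if (length(cand) > 1) cand <- cand[order(days[cand])][1] # pre-index first
  values[cand]
}

ols_slope <- function(x, y) {
  if (length(x) < 2 || stats::var(x) == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Longitudinal summaries within the index window
#'
#' For each laboratory series: the in-window minimum, maximum and ordinary
#' least-squares slope per day (`NA`, not zero, with fewer than two
#' observations). For weight: percentage change from the earliest to the
#' latest in-window measurement.
#'
#' @param days,values One patient-feature series.
#' @param window Index window in days.
#' @return Named list `min`, `max`, `slope`.
#' @export
engineer_longitudinal <- function(days, values, window = c(-90, 30)) {
  keep <- !is.na(days) & days >= window[1] & days <= window[2]
  days <- days[keep]; values <- values[keep]
  if (!length(days)) {
    return(list(min = NA_real_, max = NA_real_, slope = NA_real_))
  }
  list(min = min(values), max = max(values),
       slope = ols_slope(days, values))
}

weight_pct_change_from_series <- function(days, values, window = c(-90, 30)) {
  keep <- !is.na(days) & days >= window[1] & days <= window[2]
  days <- days[keep]; values <- values[keep]
  if (length(days) < 2) return(NA_real_)
  first <- values[which.min(days)]
  last <- values[which.max(days)]
  100 * (last - first) / first
}

#' Build the model-ready feature matrix from a cohort
#'
#' Recomputes index-window baselines and longitudinal summaries from the long
#' observation table, joins the static features, and attaches the outcome pair
#' (`time` in months, `event`). ECOG becomes a factor with an explicit
#' `"unknown"` level. The attribute `"model_features"` lists the columns a
#' prognostic model may use (see [model_features()]); `latent_true_risk` and
#' treatment columns are never in it.
#'
#' @param cohort An `rwe_cohort`.
#' @param window Index window in days.
#' @return A data.frame of class `rwe_features`.
#' @export
build_feature_matrix <- function(cohort, window = c(-90, 30)) {
  stopifnot(inherits(cohort, "rwe_cohort"))
  p <- cohort$patients
  obs <- cohort$observations
  out <- p[, c("patient_id", "age", "sex", "pdl1", "smoker", "histology",
               "year_of_dx", "time_to_met", "comorb_chf", "comorb_renal",
               "line_of_therapy")]
  ecog <- rep(NA_real_, nrow(p))
  labs <- c("creatinine", "hemoglobin", "bilirubin", "albumin")
  lab_cols <- matrix(NA_real_, nrow(p), 4 * length(labs),
                     dimnames = list(NULL, paste0(
                       rep(labs, each = 4), c("", "_min", "_max", "_slope"))))
  wpc <- rep(NA_real_, nrow(p))

  o_pid <- obs$patient_id; o_feat <- obs$feature
  o_day <- obs$day; o_val <- obs$value
  idx <- split(seq_len(nrow(obs)), o_pid)
  pid_pos <- match(names(idx), p$patient_id)
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    i <- pid_pos[k]
    feat_k <- o_feat[rows]; day_k <- o_day[rows]; val_k <- o_val[rows]
    for (lab in labs) {
      sel <- feat_k == lab
      if (!any(sel)) next
      d <- day_k[sel]; v <- val_k[sel]
      lab_cols[i, lab] <- select_index_window(d, v, window)
      lg <- engineer_longitudinal(d, v, window)
      lab_cols[i, paste0(lab, "_min")] <- lg$min
      lab_cols[i, paste0(lab, "_max")] <- lg$max
      lab_cols[i, paste0(lab, "_slope")] <- lg$slope
    }
    sel <- feat_k == "ecog"
    if (any(sel)) {
      ecog[i] <- select_index_window(day_k[sel], val_k[sel], window)
    }
    sel <- feat_k == "weight"
    if (any(sel)) {
      wpc[i] <- weight_pct_change_from_series(day_k[sel], val_k[sel], window)
    }
  }
  out$ecog <- factor(ifelse(is.na(ecog), "unknown", as.character(ecog)),
                     levels = c(as.character(0:4), "unknown"))
  out <- cbind(out, as.data.frame(lab_cols))
  out$weight_pct_change <- wpc
  out$treatment <- p$treatment
  out$time <- p$time
  out$event <- p$event
  structure(out,
            model_features = intersect(model_features(), names(out)),
            class = c("rwe_features", "data.frame"))
}

#' Fit the default imputer on training rows
#'
#' Medians of numeric model features are computed on the training rows only;
#' applying the imputer fills numeric gaps with the training median and creates
#' one binary `miss_*` indicator per imputed column, while missing ECOG stays
#' at its explicit `"unknown"` level. Imputation parameters can be persisted as
#' a JSON sidecar.
#'
#' @param features An `rwe_features` data.frame.
#' @param train_ids Patient ids of the training rows.
#' @param columns Numeric columns to impute; defaults to all numeric model
#'   features with any missing value in `features`.
#' @return An object of class `rwe_imputer`.
#' @export
fit_imputer <- function(features, train_ids = features$patient_id,
                        columns = NULL) {
  tr <- features[features$patient_id %in% train_ids, , drop = FALSE]
  model_cols <- attr(features, "model_features") %||% names(features)
  if (is.null(columns)) {
    num <- vapply(features[model_cols], is.numeric, logical(1))
    columns <- model_cols[num][vapply(model_cols[num], function(cl)
      anyNA(features[[cl]]), logical(1))]
  }
  medians <- lapply(columns, function(cl) {
    v <- tr[[cl]]
    if (all(is.na(v))) {
      stop("cannot impute column with all-missing training values: ", cl)
    }
    stats::median(v, na.rm = TRUE)
  })
  names(medians) <- columns
  structure(list(medians = medians), class = "rwe_imputer")
}

#' Apply default median imputation
#'
#' @param features An `rwe_features` data.frame.
#' @param imputer An `rwe_imputer` from [fit_imputer()] (training rows only).
#' @return The feature matrix with no missing numeric model values and one
#'   `miss_*` flag column per imputed feature.
#' @export
impute_default <- function(features, imputer) {
  stopifnot(inherits(imputer, "rwe_imputer"))
  for (cl in names(imputer$medians)) {
    miss <- is.na(features[[cl]])
    features[[paste0("miss_", cl)]] <- as.integer(miss)
    features[[cl]][miss] <- imputer$medians[[cl]]
  }
  if ("ecog" %in% names(features) && anyNA(features$ecog)) {
    features$ecog[is.na(features$ecog)] <- "unknown"
  }
  attr(features, "imputed_columns") <- names(imputer$medians)
  features
}

#' @rdname fit_imputer
#' @param path JSON file for the sidecar.
#' @export
write_imputer <- function(imputer, path) {
  jsonlite::write_json(imputer$medians, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_imputer
#' @export
read_imputer <- function(path) {
  structure(list(medians = jsonlite::read_json(path, simplifyVector = FALSE)),
            class = "rwe_imputer")
}

#' Stratified train/test split
#'
#' Assigns each patient to the training or test set with the training fraction
#' honoured within each stratum to within one patient; strata with fewer than
#' two patients go entirely to training with a warning.
#'
#' @param table A data.frame with a `patient_id` column.
#' @param fraction Training fraction, default 0.8.
#' @param stratify_by Stratification column, default `"year_of_dx"`.
#' @param seed Integer seed.
#' @return An object of class `rwe_split`: list with `assignment` (named
#'   character vector patient_id -> "train"/"test"), `stratify_by`, `fraction`.
#' @export
split_train_test <- function(table, fraction = 0.8,
                             stratify_by = "year_of_dx", seed = 1L) {
  stopifnot(stratify_by %in% names(table), fraction > 0, fraction < 1)
  set.seed(as.integer(seed))
  assignment <- rep("train", nrow(table))
  for (s in split(seq_len(nrow(table)), table[[stratify_by]])) {
    if (length(s) < 2) {
      warning("stratum with <2 patients assigned entirely to training")
      next
    }
    n_train <- round(length(s) * fraction)
    n_train <- min(max(n_train, 1L), length(s) - 1L)
    test <- sample(s, length(s) - n_train)
    assignment[test] <- "test"
  }
  names(assignment) <- table$patient_id
  structure(list(assignment = assignment, stratify_by = stratify_by,
                 fraction = fraction, seed = as.integer(seed)),
            class = "rwe_split")
}

#' @export
print.rwe_split <- function(x, ...) {
  cat("<rwe_split>", sum(x$assignment == "train"), "train /",
      sum(x$assignment == "test"), "test, stratified by", x$stratify_by, "\n")
  invisible(x)
}
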