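#' Inverse-probability-of-censoring weights at a horizon
#'
#' Computes the Kaplan-Meier estimate of the censoring survival function
#' \eqn{\hat G} (event indicator `1 - event`) and assigns each case (death at
#' or before `t`) the weight \eqn{1/\hat G(y_i-)}, i.e. the censoring survival
#' evaluated left-continuously at the case's time. Patients contributing no
#' case information at `t` (censored before `t`, or still at risk) get weight
#' zero; controls (`y > t`) enter the AUC unweighted.
#'
#' @param times Observed times (months), positive.
#' @param events Event indicators (1 = death).
#' @param t Horizon.
#' @return An object of class `rwe_ipcw`: list with `weights`, `is_case`,
#'   `is_control`, and the censoring KM (`g_times`, `g_surv`).
#' @export
censoring_weights <- function(times, events, t) {
  stopifnot(t > 0, length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  cfit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  g_minus <- function(u) {
    # left-continuous: value of G just before u (largest step time < u)
    k <- findInterval(u, cfit$time, left.open = TRUE)
    ifelse(k == 0, 1, cfit$surv[pmax(k, 1)])
  }
  is_case <- times <= t & events == 1
  is_control <- times > t
  w <- numeric(length(times))
  if (any(is_case)) {
    g <- g_minus(times[is_case])
    if (any(g <= 0)) {
      stop("censoring survival is zero at a case time; use a smaller t")
    }
    w[is_case] <- 1 / g
  }
  structure(list(weights = w, is_case = is_case, is_control = is_control,
                 g_times = cfit$time, g_surv = cfit$surv, t = t),
            class = "rwe_ipcw")
}

#' Cumulative/dynamic time-dependent AUC with IPCW
#'
#' The weighted probability that, of two random patients where patient i dies
#' by `t` and patient j survives past `t`, the model scores i at least as high
#' as j:
#' \deqn{\widehat{AUC}(t) = \frac{\sum_i \sum_j I(y_j > t) I(y_i \le t)
#'   \omega_i I(\hat f(x_j) \le \hat f(x_i))}{(\sum_j I(y_j > t))
#'   (\sum_i I(y_i \le t) \omega_i)}}
#' The printed `<=` indicator credits score ties as concordant, so an
#' all-tied score vector scores 1.0; `tie_policy = "half"` gives the usual
#' half-credit convention for cross-library comparison.
#'
#' @param times,events Observed times and event flags.
#' @param scores Risk scores, higher = higher mortality risk.
#' @param t Horizon.
#' @param weights Optional precomputed [censoring_weights()]; recomputed
#'   otherwise.
#' @param tie_policy `"le"` (default, the printed indicator) or `"half"`.
#' @return AUC in `[0, 1]`.
#' @export
td_auc <- function(times, events, scores, t, weights = NULL,
                   tie_policy = c("le", "half")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(length(scores) == length(times))
  w <- weights %||% censoring_weights(times, events, t)
  stopifnot(inherits(w, "rwe_ipcw"))
  if (!any(w$is_case) || !any(w$is_control)) {
    stop("AUC undefined at t = ", t, ": needs at least one case and control")
  }
  f_case <- scores[w$is_case]
  om <- w$weights[w$is_case]
  f_ctrl_sorted <- sort(scores[w$is_control])
  n_le <- findInterval(f_case, f_ctrl_sorted)            # controls <= f_i
  conc <- if (tie_policy == "le") {
    n_le
  } else {
    n_lt <- findInterval(f_case, f_ctrl_sorted, left.open = TRUE) # controls < f_i
    (n_le + n_lt) / 2
  }
  sum(om * conc) / (length(f_ctrl_sorted) * sum(om))
}

#' AUC curve on a 30-day grid
#'
#' Evaluates [td_auc()] at 30-day intervals (expressed as whole months) from 1
#' month through 5 years by default; grid points where the AUC is undefined
#' (no cases yet, or no controls left) are returned as `NA` and flagged.
#'
#' @inheritParams td_auc
#' @param grid Strictly increasing evaluation times, default `1:60` months.
#' @return A data.frame with columns `t`, `auc`, `defined`.
#' @export
auc_curve <- function(times, events, scores, grid = 1:60,
                      tie_policy = c("le", "half")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(all(diff(grid) > 0))
  auc <- vapply(grid, function(tt) {
    tryCatch(td_auc(times, events, scores, tt, tie_policy = tie_policy),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(t = grid, auc = auc, defined = !is.na(auc))
}

#' Bootstrap percentile interval for the time-dependent AUC
#'
#' Resamples patients with replacement, recomputing the censoring weights
#' inside every replicate, and returns a seeded percentile interval.
#'
#' @inheritParams td_auc
#' @param reps Bootstrap replicates (default 10,000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `lower`, `upper`, `level`, `reps`, `n_undefined`.
#' @export
bootstrap_auc_ci <- function(times, events, scores, t, reps = 10000,
                             level = 0.95, seed = 1L,
                             tie_policy = c("le", "half")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(reps >= 100)
  set.seed(as.integer(seed))
  n <- length(times)
  vals <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(td_auc(times[idx], events[idx], scores[idx], t,
                    tie_policy = tie_policy),
             error = function(e) NA_real_)
  }, numeric(1))
  n_undef <- sum(is.na(vals))
  if (n_undef > 0.2 * reps) {
    stop("more than 20% of bootstrap replicates had an undefined AUC")
  }
  q <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                       na.rm = TRUE, names = FALSE)
  list(lower = q[1], upper = q[2], level = level, reps = reps,
       n_undefined = n_undef)
}

#' Export an AUC curve with bootstrap bands as tidy CSV
#'
#' @param times,events,scores As in [td_auc()].
#' @param path Output CSV path.
#' @param grid Evaluation grid.
#' @param reps Bootstrap replicates per point.
#' @param seed Integer seed.
#' @return The tidy data.frame (`t`, `auc`, `lower`, `upper`), invisibly
#'   written to `path`.
#' @export
write_auc_curve <- function(times, events, scores, path, grid = 1:60,
                            reps = 1000, seed = 1L) {
  curve <- auc_curve(times, events, scores, grid)
  ci <- t(vapply(seq_along(grid), function(i) {
    if (!curve$defined[i]) return(c(NA_real_, NA_real_))
    b <- bootstrap_auc_ci(times, events, scores, grid[i], reps = reps,
                          seed = child_seed(seed, i))
    c(b$lower, b$upper)
  }, numeric(2)))
  out <- data.frame(t = curve$t, auc = curve$auc, lower = ci[, 1],
                    upper = ci[, 2])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
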