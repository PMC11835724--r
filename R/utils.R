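#' @keywords internal
"_PACKAGE"

expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a top-level seed
#'
#' Stages of the pipeline draw their own seeds from a single top-level seed via
#' a fixed counter scheme, so each stage is independently re-runnable.
#'
#' @param seed Integer top-level seed.
#' @param index Integer counter (which child stream).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  # splitmix-style integer hash, kept in 32-bit signed range
  x <- (as.double(seed) * 48271 + as.double(index) * 104729) %% 2147483647
  as.integer(x)
}

weighted_mean <- function(x, w) sum(w * x) / sum(w)

weighted_var <- function(x, w) {
  m <- weighted_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

#' Restricted mean survival time of an exponential distribution
#'
#' Closed form \eqn{(1 - e^{-\lambda\tau})/\lambda}; used by the ground-truth
#' heterogeneity audit and by tests.
#'
#' @param rate Hazard rate per month.
#' @param tau Horizon in months.
#' @return RMST in months.
#' @export
exp_rmst <- function(rate, tau) {
  stopifnot(all(rate > 0), tau > 0)
  (1 - exp(-rate * tau)) / rate
}

stop_config <- function(...) {
  stop(structure(class = c("rwe_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
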