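#' Planted truth for a survival-cutpoint simulation
#'
#' @param true_cut_quantile expression quantile (0, 1) above which hazard is
#'   multiplied.
#' @param hazard_ratio hazard multiplier for the high-expression group (> 0).
#' @param censor_rate target marginal censoring fraction in the baseline arm,
#'   in [0, 1).
#' @return a \code{survival_truth} list.
#' @export
survival_truth <- function(true_cut_quantile = 0.6, hazard_ratio = 3,
                           censor_rate = 0.3) {
  stopifnot(true_cut_quantile > 0, true_cut_quantile < 1, hazard_ratio > 0,
            censor_rate >= 0, censor_rate < 1)
  structure(list(true_cut_quantile = true_cut_quantile,
                 hazard_ratio = hazard_ratio, censor_rate = censor_rate),
            class = "survival_truth")
}

#' Simulate a survival cohort with a planted expression cutpoint
#'
#' Expression is standard normal; event times are exponential with baseline
#' rate 0.1 (arbitrary time unit), multiplied by \code{hazard_ratio} for the
#' samples above the \code{true_cut_quantile} expression quantile — the
#' proportional-hazards effect is therefore exact by construction. Censoring
#' is independent exponential with the rate that makes the baseline-arm
#' marginal censoring probability equal \code{censor_rate}
#' (\code{censor_rate = 0} gives no censoring at all).
#'
#' @param n cohort size (>= 20; below that a constrained cutpoint scan is
#'   undefined).
#' @param truth a \code{survival_truth}.
#' @param seed integer seed.
#' @return a \code{survival_cohort} data.frame (sample_id, expression, time,
#'   event) with the truth and realized cut value attached as attributes.
#' @export
simulate_survival_cohort <- function(n, truth = survival_truth(), seed) {
  if (!is.numeric(n) || n < 20) {
    stop("`n` must be >= 20: the minimum-group cutpoint scan is undefined ",
         "on smaller cohorts")
  }
  stopifnot(inherits(truth, "survival_truth"))
  n <- as.integer(n)
  base_rate <- 0.1
  with_rng_seed(seed, {
    expr <- stats::rnorm(n)
    cut_value <- stats::quantile(expr, truth$true_cut_quantile, names = FALSE)
    high <- expr > cut_value
    rate <- base_rate * ifelse(high, truth$hazard_ratio, 1)
    t_event <- stats::rexp(n, rate)
    if (truth$censor_rate > 0) {
      c_rate <- base_rate * truth$censor_rate / (1 - truth$censor_rate)
      t_cens <- stats::rexp(n, c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    cohort <- data.frame(
      sample_id = sprintf("s%04d", seq_len(n)),
      expression = expr,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE
    )
    attr(cohort, "truth") <- truth
    attr(cohort, "cut_value") <- cut_value
    class(cohort) <- c("survival_cohort", "data.frame")
    cohort
  })
}
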