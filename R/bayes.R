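# Conjugate Bayesian estimation: beta-binomial posteriors for binary endpoint
# rates, and an exponential likelihood with a conjugate gamma prior on the
# hazard (equivalently an inverse-gamma prior on the mean survival time) for
# median survival.

#' Beta-binomial conjugate update
#'
#' With `s` successes in `n` patients and a Beta(`a0`, `b0`) prior on the true
#' rate, the posterior is Beta(`a0 + s`, `b0 + n - s`). The default
#' Beta(1, 1) prior is the minimally informative uniform.
#'
#' @param s Number of successes (0 <= s <= n).
#' @param n Number of evaluable patients.
#' @param a0,b0 Prior shape parameters (default 1, 1).
#' @return Object of class `"beta_posterior"`: list with `alpha`, `beta`,
#'   `s`, `n`, `a0`, `b0`.
#' @export
#' @examples
#' beta_binomial_update(2, 26)   # Beta(3, 25)
beta_binomial_update <- function(s, n, a0 = 1, b0 = 1) {
  stop_if(a0 <= 0 || b0 <= 0, "prior parameters must be positive")
  stop_if(s < 0 || n < 0, "counts must be non-negative")
  stop_if(s > n, "successes (%s) exceed evaluable patients (%s)", s, n)
  structure(list(alpha = a0 + s, beta = b0 + n - s,
                 s = s, n = n, a0 = a0, b0 = b0),
            class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) posterior  [%g/%g events, Beta(%g, %g) prior]\n",
              x$alpha, x$beta, x$s, x$n, x$a0, x$b0))
  invisible(x)
}

#' Summarise a beta posterior
#'
#' Point estimate is the posterior median (the 0.5 quantile of the
#' regularised-incomplete-beta inverse); the credible interval is
#' equal-tailed. When `threshold` is supplied, `prob_exceeds` is the
#' posterior probability that the true rate exceeds it — the quantity the
#' GO/NO-GO rule acts on.
#'
#' @param p A `"beta_posterior"`.
#' @param level Credible level (default 0.95).
#' @param threshold Clinically relevant rate, or `NULL`.
#' @return Object of class `"posterior_summary"`: `point`, `ci_low`,
#'   `ci_high`, `level`, `prob_exceeds`, `threshold`.
#' @export
#' @examples
#' summarise_beta(beta_binomial_update(2, 26))            # 9.8% (2.4-24.3)
#' summarise_beta(beta_binomial_update(6, 26), threshold = 0.30)
summarise_beta <- function(p, level = 0.95, threshold = NULL) {
  stopifnot(inherits(p, "beta_posterior"), level > 0, level < 1)
  tail <- (1 - level) / 2
  q <- qbeta(c(tail, 0.5, 1 - tail), p$alpha, p$beta)
  pe <- if (is.null(threshold)) NA_real_ else
    pbeta(threshold, p$alpha, p$beta, lower.tail = FALSE)
  new_posterior_summary(point = q[2L], ci_low = q[1L], ci_high = q[3L],
                        level = level, prob_exceeds = pe,
                        threshold = if (is.null(threshold)) NA_real_ else threshold)
}

new_posterior_summary <- function(point, ci_low, ci_high, level,
                                  prob_exceeds = NA_real_,
                                  threshold = NA_real_) {
  stop_if(!(ci_low <= point && point <= ci_high),
          "credible interval does not bracket the point estimate")
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 level = level, prob_exceeds = prob_exceeds,
                 threshold = threshold),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  cat(sprintf("%s (%g%% CrI %s-%s)",
              format(x$point, digits = digits),
              100 * x$level,
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits)))
  if (!is.na(x$prob_exceeds))
    cat(sprintf("  P(> %g) = %s", x$threshold,
                format(x$prob_exceeds, digits = digits)))
  cat("\n")
  invisible(x)
}

#' Exponential survival likelihood, conjugate gamma/inverse-gamma update
#'
#' Assumes exponentially distributed survival times with hazard `lambda`.
#' A Gamma(`a0` shape, `b0` rate) prior on the hazard — equivalently an
#' inverse-gamma IG(`a0`, `b0`) prior on the mean survival time — is
#' conjugate: with `d` events and total follow-up time `T` (events plus
#' censored), the posterior is Gamma(`a0 + d`, `b0 + T`). Censored
#' observations contribute follow-up time only. The IG(0.001, 0.001)
#' default is minimally informative.
#'
#' @param times Positive follow-up times (any consistent unit).
#' @param events Logical vector, `TRUE` = event observed.
#' @param a0,b0 Prior shape and rate/scale (default 0.001, 0.001).
#' @return Object of class `"surv_posterior"`: `shape`, `rate_total`,
#'   `d` (events), `total_time`, `a0`, `b0`.
#' @export
#' @examples
#' exponential_ig_update(c(2, 4, 6), c(TRUE, TRUE, FALSE))  # Gamma(2.001, 12.001)
exponential_ig_update <- function(times, events, a0 = 0.001, b0 = 0.001) {
  stop_if(length(times) != length(events), "times and events differ in length")
  stop_if(any(times <= 0), "all follow-up times must be positive")
  stop_if(a0 <= 0 || b0 <= 0, "prior parameters must be positive")
  events <- as.logical(events)
  structure(list(shape = a0 + sum(events), rate_total = b0 + sum(times),
                 d = sum(events), total_time = sum(times), a0 = a0, b0 = b0),
            class = "surv_posterior")
}

#' @export
print.surv_posterior <- function(x, ...) {
  cat(sprintf("Gamma(%g, %g) posterior on the hazard  [%d events, total time %g]\n",
              x$shape, x$rate_total, x$d, x$total_time))
  invisible(x)
}

#' Posterior summary of the median survival time
#'
#' Under the exponential model the median survival is `M = log(2) / lambda`,
#' a strictly decreasing transform of the hazard, so posterior quantiles of
#' `M` are the reversed, transformed quantiles of the Gamma posterior on
#' `lambda`: the posterior median of `M` is `log(2)` over the Gamma median,
#' and the equal-tailed CI endpoints are `log(2)` over the upper and lower
#' Gamma quantiles respectively (note the order reversal). The summary is
#' scale-equivariant: doubling all input times doubles all three values.
#'
#' @param g A `"surv_posterior"`.
#' @param level Credible level (default 0.95).
#' @return A `"posterior_summary"` in the time unit of the input.
#' @export
summarise_median_survival <- function(g, level = 0.95) {
  stopifnot(inherits(g, "surv_posterior"), level > 0, level < 1)
  tail <- (1 - level) / 2
  q_lambda <- qgamma(c(1 - tail, 0.5, tail), shape = g$shape, rate = g$rate_total)
  m <- log(2) / q_lambda
  new_posterior_summary(point = m[2L], ci_low = m[1L], ci_high = m[3L],
                        level = level)
}

#' Format a rate summary the way the trial reports it
#'
#' Percent to one decimal place: `"9.8 (2.4-24.3)"`.
#'
#' @param s A `"posterior_summary"` on the probability scale.
#' @return Character scalar.
#' @export
format_rate_summary <- function(s) {
  sprintf("%.1f (%.1f-%.1f)", 100 * s$point, 100 * s$ci_low, 100 * s$ci_high)
}

#' Format a median-survival summary in months to one decimal place
#'
#' @param s A `"posterior_summary"` in days.
#' @param days_per_month Conversion factor (default 365.25 / 12).
#' @return Character scalar, e.g. `"6.1 (4.2-9.3)"`.
#' @export
format_survival_summary <- function(s, days_per_month = 365.25 / 12) {
  sprintf("%.1f (%.1f-%.1f)", s$point / days_per_month,
          s$ci_low / days_per_month, s$ci_high / days_per_month)
}
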