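# GO/NO-GO screening decisions and simulated operating characteristics of
# the single-look design.

#' Screening decision configuration
#'
#' `relevant_rate_or` / `relevant_rate_dcb` are the minimum clinically
#' relevant true rates for the two co-primary endpoints; a cohort screens GO
#' when the posterior probability of exceeding the relevant rate reaches
#' `go_pp_cutoff`. The 0.30 defaults are the thresholds consistent with the
#' design's posterior-probability reporting; the 0.90 cutoff is a
#' conventional screening default and is configurable.
#'
#' @param relevant_rate_or Relevant true OR rate (default 0.30).
#' @param relevant_rate_dcb Relevant true DCB rate (default 0.30).
#' @param go_pp_cutoff Posterior-probability cutoff for GO (default 0.90).
#' @param target_n Planned cohort size (default 30).
#' @return Object of class `"decision_config"`.
#' @export
decision_config <- function(relevant_rate_or = 0.30, relevant_rate_dcb = 0.30,
                            go_pp_cutoff = 0.90, target_n = 30L) {
  stop_if(relevant_rate_or <= 0 || relevant_rate_or >= 1 ||
            relevant_rate_dcb <= 0 || relevant_rate_dcb >= 1,
          "relevant rates must lie in (0, 1)")
  stop_if(go_pp_cutoff <= 0 || go_pp_cutoff >= 1,
          "go_pp_cutoff must lie in (0, 1)")
  structure(list(relevant_rate_or = relevant_rate_or,
                 relevant_rate_dcb = relevant_rate_dcb,
                 go_pp_cutoff = go_pp_cutoff,
                 target_n = as.integer(target_n)),
            class = "decision_config")
}

#' GO/NO-GO decision from a posterior summary
#'
#' GO if and only if the posterior probability that the true rate exceeds
#' the configured clinically relevant threshold reaches the cutoff.
#'
#' @param summary A `"posterior_summary"` carrying `prob_exceeds` computed at
#'   the configured relevant rate.
#' @param cfg A [decision_config()].
#' @return `"GO"` or `"NO-GO"`.
#' @export
#' @examples
#' s <- summarise_beta(beta_binomial_update(6, 26), threshold = 0.30)
#' decide(s, decision_config())   # "NO-GO": P(rate > 0.30) = 0.26 < 0.90
decide <- function(summary, cfg = decision_config()) {
  stopifnot(inherits(summary, "posterior_summary"))
  stop_if(is.na(summary$prob_exceeds),
          "posterior summary carries no exceedance probability")
  if (summary$prob_exceeds >= cfg$go_pp_cutoff) "GO" else "NO-GO"
}

#' Simulated operating characteristics of the screening rule
#'
#' For each true rate on the grid, simulates `n_sims` trials of `n` patients
#' with binomial outcomes, runs the beta-binomial update and the decision
#' rule, and reports the fraction of GO decisions with its Monte-Carlo
#' standard error. Fully reproducible from `seed`.
#'
#' @param cfg A [decision_config()].
#' @param true_rates Numeric vector of true success rates in `[0, 1]`.
#' @param n Patients per simulated trial (default `cfg$target_n`).
#' @param n_sims Simulated trials per grid point (default 2000).
#' @param seed Integer RNG seed.
#' @param threshold Relevant rate to test against (default
#'   `cfg$relevant_rate_or`).
#' @return Object of class `"operating_characteristics"`: data frame with
#'   columns `true_rate`, `p_go`, `mc_se`, plus attributes `n`, `n_sims`,
#'   `seed`.
#' @export
operating_characteristics <- function(cfg = decision_config(),
                                      true_rates = seq(0, 1, by = 0.1),
                                      n = cfg$target_n, n_sims = 2000L,
                                      seed = 1L,
                                      threshold = cfg$relevant_rate_or) {
  stop_if(n_sims < 1L, "n_sims must be at least 1")
  set.seed(seed)
  rows <- lapply(true_rates, function(r) {
    s <- rbinom(n_sims, size = n, prob = r)
    # decision depends on data only through s: decide once per distinct count
    go_by_s <- vapply(0:n, function(k) {
      post <- summarise_beta(beta_binomial_update(k, n), threshold = threshold)
      decide(post, cfg) == "GO"
    }, logical(1))
    p_go <- mean(go_by_s[s + 1L])
    data.frame(true_rate = r, p_go = p_go,
               mc_se = sqrt(p_go * (1 - p_go) / n_sims))
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  attr(out, "n_sims") <- n_sims
  attr(out, "seed") <- seed
  attr(out, "threshold") <- threshold
  class(out) <- c("operating_characteristics", "data.frame")
  out
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics: n = %d per trial, %d sims, seed %d\n",
              attr(x, "n"), attr(x, "n_sims"), attr(x, "seed")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
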