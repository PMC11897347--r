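# The central fit: compose endpoint derivation, conjugate posterior
# estimation and the screening decision rule into one classed object.

#' Analysis configuration
#'
#' Collects every tunable of the analysis pipeline: the Beta(1,1) prior on
#' binary endpoint rates, the IG(0.001, 0.001) prior of the exponential
#' survival model, the RECIST confirmation window (28 days), the DCB
#' schedule (fourth protocol CT, minimum 154 days = 22 weeks), the analysis
#' population, the handling of not-evaluable DCB (counted as failure by
#' default), the days-to-months conversion, and the screening decision
#' thresholds.
#'
#' @param rate_prior Length-2 numeric, Beta prior shapes (default `c(1, 1)`).
#' @param surv_prior Length-2 numeric, IG prior shape/scale (default
#'   `c(0.001, 0.001)`).
#' @param confirm_window_days RECIST confirmation window (default 28).
#' @param n_assessments,min_days DCB schedule (defaults 4 and 154).
#' @param population `"per_protocol"` or `"all"`.
#' @param na_rule `"failure"` or `"exclude"` for not-evaluable DCB.
#' @param level Credible level (default 0.95).
#' @param days_per_month Conversion factor (default 365.25/12).
#' @param decision A [decision_config()].
#' @return Object of class `"screen_config"`.
#' @export
screen_config <- function(rate_prior = c(1, 1),
                          surv_prior = c(0.001, 0.001),
                          confirm_window_days = 28,
                          n_assessments = 4L, min_days = 154L,
                          population = c("per_protocol", "all"),
                          na_rule = c("failure", "exclude"),
                          level = 0.95,
                          days_per_month = 365.25 / 12,
                          decision = decision_config()) {
  structure(list(
    rate_prior = rate_prior, surv_prior = surv_prior,
    confirm_window_days = confirm_window_days,
    n_assessments = as.integer(n_assessments),
    min_days = as.integer(min_days),
    population = match.arg(population),
    na_rule = match.arg(na_rule),
    level = level, days_per_month = days_per_month,
    decision = decision
  ), class = "screen_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [screen_config()] (decision thresholds under
#' a `decision:` block); keys absent from the file keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"screen_config"`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dec_args <- raw$decision
  raw$decision <- NULL
  known <- names(formals(screen_config))
  unknown <- setdiff(names(raw), known)
  stop_if(length(unknown) > 0L, "unknown config key(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- do.call(screen_config, raw)
  if (!is.null(dec_args)) cfg$decision <- do.call(decision_config, dec_args)
  cfg
}

#' Fit the Bayesian screening analysis to a patient cohort
#'
#' Derives per-patient endpoints, forms conjugate posteriors for the
#' co-primary binary endpoints (objective response, durable clinical
#' benefit) per cohort, fits the exponential survival model to PFS, TTP and
#' OS, and applies the GO/NO-GO screening rule to each cohort's co-primary
#' posteriors.
#'
#' @param patients List of [patient_record] objects (e.g. from
#'   [read_patients()] or [generate_patients()]).
#' @param config A [screen_config()].
#' @return Object of class `"trial_screen"` with components
#'   \describe{
#'     \item{endpoints}{per-patient endpoint data frame}
#'     \item{rates}{per cohort x endpoint: counts, posterior median, CrI,
#'       exceedance probability, decision}
#'     \item{survival}{per cohort x endpoint: events, total follow-up days,
#'       posterior median of median survival with CrI, in days and months}
#'     \item{config}{the configuration used}
#'   }
#'   Methods: `print`, `summary`, `coef`, `plot`, `simulate`.
#' @export
#' @examples
#' fit <- trial_screen(generate_patients(generator_config(seed = 7)))
#' summary(fit)
#' coef(fit)
trial_screen <- function(patients, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  endpoints <- derive_endpoints(patients,
                                confirm_window_days = config$confirm_window_days,
                                n_assessments = config$n_assessments,
                                min_days = config$min_days)
  a0 <- config$rate_prior[1L]; b0 <- config$rate_prior[2L]

  rate_rows <- list()
  for (ep in c("objective_response", "dcb")) {
    threshold <- if (ep == "objective_response")
      config$decision$relevant_rate_or else config$decision$relevant_rate_dcb
    counts <- cohort_counts(endpoints, endpoint = ep,
                            population = config$population,
                            na_rule = config$na_rule)
    for (i in seq_len(nrow(counts))) {
      post <- beta_binomial_update(counts$successes[i], counts$n[i], a0, b0)
      s <- summarise_beta(post, level = config$level, threshold = threshold)
      rate_rows[[length(rate_rows) + 1L]] <- data.frame(
        cohort = counts$cohort[i], endpoint = ep,
        successes = counts$successes[i], n = counts$n[i],
        point = s$point, ci_low = s$ci_low, ci_high = s$ci_high,
        prob_exceeds = s$prob_exceeds, threshold = threshold,
        decision = decide(s, config$decision),
        stringsAsFactors = FALSE)
    }
  }
  rates <- if (length(rate_rows)) do.call(rbind, rate_rows) else data.frame()

  surv_rows <- list()
  e <- endpoints
  if (nrow(e) > 0L && config$population == "per_protocol")
    e <- e[e$per_protocol, , drop = FALSE]
  if (nrow(e) > 0L) {
    for (co in sort(unique(e$cohort))) {
      sub <- e[e$cohort == co, , drop = FALSE]
      for (ep in c("pfs", "ttp", "os")) {
        times <- sub[[paste0(ep, "_days")]]
        events <- sub[[paste0(ep, "_event")]]
        post <- exponential_ig_update(times, events,
                                      config$surv_prior[1L], config$surv_prior[2L])
        s <- summarise_median_survival(post, level = config$level)
        surv_rows[[length(surv_rows) + 1L]] <- data.frame(
          cohort = co, endpoint = ep, events = post$d,
          total_days = post$total_time,
          median_days = s$point, ci_low_days = s$ci_low, ci_high_days = s$ci_high,
          median_months = s$point / config$days_per_month,
          ci_low_months = s$ci_low / config$days_per_month,
          ci_high_months = s$ci_high / config$days_per_month,
          stringsAsFactors = FALSE)
      }
    }
  }
  survival <- if (length(surv_rows)) do.call(rbind, surv_rows) else data.frame()

  structure(list(endpoints = endpoints, rates = rates, survival = survival,
                 config = config, n_patients = length(patients),
                 call = match.call()),
            class = "trial_screen")
}

#' @export
print.trial_screen <- function(x, ...) {
  cat("Bayesian screening analysis\n")
  cat(sprintf("  %d patient(s), %s population; Beta(%g, %g) rate prior\n",
              x$n_patients, x$config$population,
              x$config$rate_prior[1L], x$config$rate_prior[2L]))
  if (nrow(x$rates) > 0L) {
    dec <- x$rates[x$rates$endpoint == "dcb", ]
    for (i in seq_len(nrow(dec)))
      cat(sprintf("  %s: DCB %d/%d, P(rate > %.2f) = %.2f -> %s\n",
                  dec$cohort[i], dec$successes[i], dec$n[i], dec$threshold[i],
                  dec$prob_exceeds[i], dec$decision[i]))
  }
  invisible(x)
}

#' Summarise a fitted screening analysis
#'
#' Formats each cohort x endpoint posterior the way the trial reports it:
#' rates as percent to one decimal with the 95% CrI, exceedance
#' probabilities to two decimals, median survival in months to one decimal.
#'
#' @param object A `"trial_screen"`.
#' @param ... Unused.
#' @return A `"summary.trial_screen"`: list of formatted data frames
#'   `rates` and `survival`.
#' @export
summary.trial_screen <- function(object, ...) {
  r <- object$rates
  rate_tab <- if (nrow(r) > 0L) data.frame(
    cohort = r$cohort, endpoint = r$endpoint,
    events = sprintf("%d/%d", r$successes, r$n),
    estimate = sprintf("%.1f (%.1f-%.1f)", 100 * r$point, 100 * r$ci_low,
                       100 * r$ci_high),
    pp = sprintf("%.2f", r$prob_exceeds),
    decision = r$decision,
    stringsAsFactors = FALSE) else data.frame()
  s <- object$survival
  surv_tab <- if (nrow(s) > 0L) data.frame(
    cohort = s$cohort, endpoint = toupper(s$endpoint),
    events = s$events,
    median_months = sprintf("%.1f (%.1f-%.1f)", s$median_months,
                            s$ci_low_months, s$ci_high_months),
    stringsAsFactors = FALSE) else data.frame()
  structure(list(rates = rate_tab, survival = surv_tab,
                 population = object$config$population),
            class = "summary.trial_screen")
}

#' @export
print.summary.trial_screen <- function(x, ...) {
  cat(sprintf("Co-primary endpoint posteriors (%s population), %% with 95%% CrI:\n",
              x$population))
  if (nrow(x$rates)) print.data.frame(x$rates, row.names = FALSE)
  cat("\nMedian survival times (months, 95% CrI):\n")
  if (nrow(x$survival)) print.data.frame(x$survival, row.names = FALSE)
  invisible(x)
}

#' Posterior medians of the fitted rates
#'
#' @param object A `"trial_screen"`.
#' @param ... Unused.
#' @return Named numeric vector `<cohort>.<endpoint>` of posterior median
#'   rates (probability scale).
#' @export
coef.trial_screen <- function(object, ...) {
  r <- object$rates
  setNames(r$point, paste(r$cohort, r$endpoint, sep = "."))
}

#' Plot a fitted screening analysis
#'
#' `type = "waterfall"` draws the best-percentage-change waterfall for the
#' analysis population (patients without a post-baseline measurement appear
#' at the +100% default); `type = "forest"` draws the per-cohort co-primary
#' rate posteriors with their credible intervals and the clinically relevant
#' threshold.
#'
#' @param x A `"trial_screen"`.
#' @param type `"waterfall"` or `"forest"`.
#' @param ... Passed to the underlying graphics calls.
#' @return `x`, invisibly.
#' @export
plot.trial_screen <- function(x, type = c("waterfall", "forest"), ...) {
  type <- match.arg(type)
  if (type == "waterfall") {
    e <- x$endpoints
    if (x$config$population == "per_protocol") e <- e[e$per_protocol, ]
    v <- sort(e$best_pct_change, decreasing = TRUE)
    barplot(v, col = "grey40", border = NA,
            ylab = "Best % change in target-lesion sum",
            main = "Waterfall of best response", ...)
    abline(h = c(-30, 20), lty = 2, col = "red")
  } else {
    r <- x$rates
    y <- seq_len(nrow(r))
    plot(100 * r$point, y, xlim = c(0, 100), pch = 16, yaxt = "n",
         xlab = "True rate (%)", ylab = "",
         main = "Co-primary endpoint posteriors", ...)
    segments(100 * r$ci_low, y, 100 * r$ci_high, y)
    axis(2, at = y, labels = paste(r$cohort, r$endpoint), las = 1, cex.axis = 0.7)
    abline(v = 100 * unique(r$threshold), col = "red", lty = 2)
  }
  invisible(x)
}

#' Posterior-predictive simulation of cohort outcomes
#'
#' Draws replicate success counts for each cohort x endpoint from the
#' beta-binomial posterior predictive distribution at the observed cohort
#' sizes.
#'
#' @param object A `"trial_screen"`.
#' @param nsim Number of replicates (default 1).
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` rows per cohort x endpoint: `cohort`,
#'   `endpoint`, `sim`, `successes`, `n`.
#' @export
simulate.trial_screen <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  r <- object$rates
  rows <- lapply(seq_len(nrow(r)), function(i) {
    a <- object$config$rate_prior[1L] + r$successes[i]
    b <- object$config$rate_prior[2L] + r$n[i] - r$successes[i]
    p <- rbeta(nsim, a, b)
    data.frame(cohort = r$cohort[i], endpoint = r$endpoint[i],
               sim = seq_len(nsim),
               successes = rbinom(nsim, size = r$n[i], prob = p),
               n = r$n[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
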