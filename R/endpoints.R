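# Derivation of the trial's co-primary and secondary efficacy endpoints from
# longitudinal RECIST assessment series.

RESPONSE_CATEGORIES <- c("CR", "PR")

#' Confirmed objective response under RECIST v1.1
#'
#' A patient has an objective response when some assessment is CR or PR and a
#' later assessment at least `confirm_window_days` after it is also CR or PR,
#' with no intervening progressive disease. The 28-day default confirmation
#' window is the RECIST v1.1 convention.
#'
#' @param p A [patient_record].
#' @param confirm_window_days Minimum days between the initial and confirming
#'   response assessments (default 28).
#' @return `TRUE`/`FALSE`. An empty assessment series returns `FALSE`.
#' @export
derive_objective_response <- function(p, confirm_window_days = 28) {
  a <- p$assessments
  if (nrow(a) < 2L) return(FALSE)
  resp <- which(a$recist %in% RESPONSE_CATEGORIES)
  for (i in resp) {
    later <- resp[resp > i & a$day[resp] - a$day[i] >= confirm_window_days]
    for (j in later) {
      between <- a$recist[seq.int(i, j)]
      if (!any(between == "PD")) return(TRUE)
    }
  }
  FALSE
}

#' Durable clinical benefit at the fourth protocol CT
#'
#' DCB is reached when the patient is progression-free (no PD assessment, no
#' death) at the `n_assessments`-th on-treatment CT, provided that CT falls at
#' or beyond `min_days` (22 weeks = 154 days, the minimum time at which the
#' threshold can be met on a 6-weekly schedule whose fourth scan is at ~24
#' weeks). Progression or death before that point returns `FALSE`; follow-up
#' ending earlier without progression is not evaluable (`NA`).
#'
#' @param p A [patient_record].
#' @param n_assessments Which protocol CT defines the endpoint (default 4).
#' @param min_days Minimum day for the qualifying CT (default 154).
#' @return `TRUE`, `FALSE`, or `NA` (not evaluable).
#' @export
derive_dcb <- function(p, n_assessments = 4L, min_days = 154L) {
  a <- p$assessments
  pd_day <- if (any(a$recist == "PD")) min(a$day[a$recist == "PD"]) else Inf
  death_day <- if (p$os_event) p$os_days else Inf
  prog_day <- if (!is.na(p$progression_day)) p$progression_day else Inf
  event_day <- min(pd_day, death_day, prog_day)

  non_pd <- a[a$recist != "PD" & a$day < event_day, , drop = FALSE]
  if (nrow(non_pd) >= n_assessments) {
    nth_day <- non_pd$day[n_assessments]
    if (nth_day >= min_days && event_day > nth_day) return(TRUE)
    # fourth CT earlier than the minimum: any later progression-free CT past
    # the threshold still qualifies
    past <- non_pd$day[non_pd$day >= min_days]
    if (length(past) > 0L && event_day > min(past)) return(TRUE)
  }
  if (is.finite(event_day)) return(FALSE)
  # no progression or death observed, but the series never confirms
  # progression-free status at a qualifying CT
  NA
}

#' Survival endpoint triple (PFS, TTP, OS)
#'
#' PFS events are progression or death, whichever comes first; TTP events are
#' progression only, with death before progression censoring TTP at the death
#' date; patients without an event are censored at last contact. OS is passed
#' through from the record. By construction `ttp_days == pfs_days` for every
#' patient and a TTP event implies a PFS event.
#'
#' @param p A [patient_record].
#' @return Named list: `pfs_days`, `pfs_event`, `ttp_days`, `ttp_event`,
#'   `os_days`, `os_event`.
#' @export
derive_survival <- function(p) {
  prog <- p$progression_day
  if (!is.na(prog)) {
    pfs_days <- prog; pfs_event <- TRUE
    ttp_days <- prog; ttp_event <- TRUE
  } else if (p$os_event) {
    pfs_days <- p$os_days; pfs_event <- TRUE
    ttp_days <- p$os_days; ttp_event <- FALSE  # death censors TTP
  } else {
    pfs_days <- p$last_contact_day; pfs_event <- FALSE
    ttp_days <- p$last_contact_day; ttp_event <- FALSE
  }
  list(pfs_days = as.integer(pfs_days), pfs_event = pfs_event,
       ttp_days = as.integer(ttp_days), ttp_event = ttp_event,
       os_days = p$os_days, os_event = p$os_event)
}

#' Best percentage change in target-lesion sum
#'
#' `100 * (min post-baseline target sum - baseline) / baseline`. Patients who
#' discontinued without returning a post-baseline measurement are assigned the
#' default of +100% (the convention used on waterfall plots). The result is
#' invariant under uniform rescaling of all lesion sums and bounded below by
#' -100.
#'
#' @param p A [patient_record].
#' @return Percent change (real, >= -100).
#' @export
best_pct_change <- function(p) {
  post <- p$assessments$target_sum_mm[p$assessments$day > 0]
  post <- post[!is.na(post)]
  if (length(post) == 0L) return(100)
  base <- p$baseline_target_sum_mm
  stop_if(is.na(base), "baseline target sum missing with post-baseline measurements [patient %s]",
          p$patient_id)
  stop_if(base == 0, "baseline target sum is zero: percent change undefined [patient %s]",
          p$patient_id)
  100 * (min(post) - base) / base
}

#' Derive the full endpoint set for a list of patients
#'
#' @param patients List of [patient_record] objects.
#' @param confirm_window_days Passed to [derive_objective_response()].
#' @param n_assessments,min_days Passed to [derive_dcb()].
#' @return Data frame with one row per patient: `patient_id`, `cohort`,
#'   `per_protocol`, `objective_response`, `dcb` (logical, `NA` = not
#'   evaluable), `pfs_days`, `pfs_event`, `ttp_days`, `ttp_event`, `os_days`,
#'   `os_event`, `best_pct_change`.
#' @export
derive_endpoints <- function(patients, confirm_window_days = 28,
                             n_assessments = 4L, min_days = 154L) {
  rows <- lapply(patients, function(p) {
    s <- derive_survival(p)
    data.frame(
      patient_id = p$patient_id,
      cohort = p$cohort,
      per_protocol = p$per_protocol,
      objective_response = derive_objective_response(p, confirm_window_days),
      dcb = derive_dcb(p, n_assessments, min_days),
      pfs_days = s$pfs_days, pfs_event = s$pfs_event,
      ttp_days = s$ttp_days, ttp_event = s$ttp_event,
      os_days = s$os_days, os_event = s$os_event,
      best_pct_change = best_pct_change(p),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Per-cohort success counts for a binary endpoint
#'
#' Counts endpoint successes and evaluable denominators per cohort. With the
#' default conservative rule, patients whose DCB is not evaluable stay in the
#' denominator as non-successes (intention-to-treat within the chosen
#' population); set `na_rule = "exclude"` to drop them.
#'
#' @param endpoints Data frame from [derive_endpoints()].
#' @param endpoint `"objective_response"` or `"dcb"`.
#' @param population `"per_protocol"` (default) or `"all"`.
#' @param na_rule `"failure"` (default) or `"exclude"`.
#' @return Data frame with columns `cohort`, `successes`, `n`.
#' @export
cohort_counts <- function(endpoints,
                          endpoint = c("objective_response", "dcb"),
                          population = c("per_protocol", "all"),
                          na_rule = c("failure", "exclude")) {
  endpoint <- match.arg(endpoint)
  population <- match.arg(population)
  na_rule <- match.arg(na_rule)
  e <- endpoints
  if (population == "per_protocol") e <- e[e$per_protocol, , drop = FALSE]
  if (nrow(e) == 0L)
    return(data.frame(cohort = character(), successes = integer(),
                      n = integer(), stringsAsFactors = FALSE))
  v <- e[[endpoint]]
  if (na_rule == "exclude") {
    e <- e[!is.na(v), , drop = FALSE]
    v <- e[[endpoint]]
    if (nrow(e) == 0L)
      return(data.frame(cohort = character(), successes = integer(),
                        n = integer(), stringsAsFactors = FALSE))
  }
  v[is.na(v)] <- FALSE
  agg <- tapply(v, e$cohort, function(x) c(sum(x), length(x)))
  cohorts <- sort(names(agg))
  data.frame(
    cohort = cohorts,
    successes = as.integer(vapply(agg[cohorts], `[`, numeric(1), 1L)),
    n = as.integer(vapply(agg[cohorts], `[`, numeric(1), 2L)),
    stringsAsFactors = FALSE
  )
}
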