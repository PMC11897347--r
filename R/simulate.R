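# Seeded synthetic-cohort generator. Emulates the three-cohort trial
# structure the analysis assumes: exponential latent progression and death
# times, CT assessments on a 6-weekly grid (progression is interval-censored
# onto the grid, death observed exactly), confirmation-compatible responder
# series, and per-gene ctDNA detectability with post-treatment odds
# multipliers and insufficient-DNA sample dropouts.

DAYS_PER_MONTH <- 365.25 / 12

#' Synthetic trial generator configuration
#'
#' Defaults encode the emulated study conditions: three cohorts of 5/30/19
#' patients, ~11% per-protocol exclusion, a low (8%) true objective-response
#' rate, moderate durable-clinical-benefit rates (24% in the double-mutant
#' cohort, 15% elsewhere), exponential overall survival with cohort medians
#' of 6-10 months, progression-free survival median 2.5 months, CT scans
#' every 42 days, 28-day treatment cycles, rare administrative dropout
#' (median 60 months), 25% insufficient-DNA plasma samples, and a 22-gene
#' ctDNA panel in which SMARCA4 and FOXP1 carry post-treatment enrichment
#' (odds multipliers chosen so expected detection frames match ~3/36 vs
#' 11/27 and ~0/36 vs 4/27) while the remaining genes are null.
#'
#' @param cohort_sizes Named integer vector of registered patients per cohort.
#' @param per_protocol_exclusion_prob Probability a patient is excluded from
#'   the per-protocol population.
#' @param true_or_rate,true_dcb_rate Named per-cohort true rates.
#' @param os_median_months,pfs_median_months Named per-cohort exponential
#'   medians, months.
#' @param dropout_median_months Median of the independent exponential
#'   censoring time.
#' @param ct_interval_days Protocol CT spacing (default 42 = 6 weeks).
#' @param cycle_days Treatment cycle length (default 28).
#' @param gene_panel Character vector of panel genes.
#' @param baseline_detect_prob Named per-gene baseline detection probability.
#' @param post_odds_multiplier Named per-gene post-treatment odds multiplier
#'   (1 = null gene).
#' @param insufficient_dna_prob Probability a plasma sample is insufficient
#'   (<9 ng).
#' @param seed Integer seed; all sub-streams derive from it.
#' @return Object of class `"generator_config"`.
#' @export
generator_config <- function(cohort_sizes = c(B1 = 5L, B2D = 30L, B2S = 19L),
                             per_protocol_exclusion_prob = 0.11,
                             true_or_rate = c(B1 = 0.08, B2D = 0.08, B2S = 0.08),
                             true_dcb_rate = c(B1 = 0.15, B2D = 0.24, B2S = 0.15),
                             os_median_months = c(B1 = 7.0, B2D = 6.1, B2S = 9.8),
                             pfs_median_months = c(B1 = 2.5, B2D = 2.5, B2S = 2.5),
                             dropout_median_months = 60,
                             ct_interval_days = 42L,
                             cycle_days = 28L,
                             gene_panel = default_gene_panel(),
                             baseline_detect_prob = default_baseline_detect_prob(),
                             post_odds_multiplier = default_post_odds_multiplier(),
                             insufficient_dna_prob = 0.25,
                             seed = 1L) {
  labels <- names(cohort_sizes)
  stop_if(is.null(labels) || any(!nzchar(labels)), "cohort_sizes must be named")
  for (m in list(true_or_rate, true_dcb_rate, os_median_months, pfs_median_months))
    stop_if(!all(labels %in% names(m)),
            "per-cohort maps must cover every cohort label")
  stop_if(any(true_or_rate < 0 | true_or_rate > 1) ||
            any(true_dcb_rate < 0 | true_dcb_rate > 1) ||
            per_protocol_exclusion_prob < 0 || per_protocol_exclusion_prob > 1 ||
            insufficient_dna_prob < 0 || insufficient_dna_prob > 1,
          "probabilities must lie in [0, 1]")
  stop_if(any(os_median_months <= 0) || any(pfs_median_months <= 0),
          "survival medians must be positive")
  stop_if(!all(gene_panel %in% names(baseline_detect_prob)) ||
            !all(gene_panel %in% names(post_odds_multiplier)),
          "gene maps must cover the panel")
  structure(list(
    cohort_sizes = cohort_sizes,
    per_protocol_exclusion_prob = per_protocol_exclusion_prob,
    true_or_rate = true_or_rate, true_dcb_rate = true_dcb_rate,
    os_median_months = os_median_months, pfs_median_months = pfs_median_months,
    dropout_median_months = dropout_median_months,
    ct_interval_days = as.integer(ct_interval_days),
    cycle_days = as.integer(cycle_days),
    gene_panel = gene_panel,
    baseline_detect_prob = baseline_detect_prob,
    post_odds_multiplier = post_odds_multiplier,
    insufficient_dna_prob = insufficient_dna_prob,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @rdname generator_config
#' @export
default_gene_panel <- function() {
  c("SMARCA4", "FOXP1", "TP53", "KRAS", "STK11", "EGFR", "KEAP1", "SMAD4",
    "BRAF", "PIK3CA", "PTEN", "RB1", "CDKN2A", "NF1", "ARID1A", "MET",
    "ALK", "ROS1", "RET", "ERBB2", "ATM", "CTNNB1")
}

#' @rdname generator_config
#' @export
default_baseline_detect_prob <- function() {
  p <- setNames(rep(0.10, length(default_gene_panel())), default_gene_panel())
  p[c("TP53", "KRAS", "STK11")] <- c(0.50, 0.45, 0.50)
  p["SMARCA4"] <- 0.083
  p["FOXP1"] <- 0.02
  p
}

#' @rdname generator_config
#' @export
default_post_odds_multiplier <- function() {
  m <- setNames(rep(1, length(default_gene_panel())), default_gene_panel())
  m["SMARCA4"] <- 7.6   # 8.3% baseline -> ~40.7% post
  m["FOXP1"] <- 8.6     # ~2% baseline -> ~15% post
  m
}

rexp_median <- function(n, median_days) rexp(n, rate = log(2) / median_days)

# exponential draw truncated to (lo, hi); inverse-CDF so a single uniform is
# consumed per draw
rexp_trunc <- function(rate, lo, hi) {
  u <- runif(1, pexp(lo, rate), pexp(hi, rate))
  qexp(u, rate)
}

#' Generate a synthetic patient cohort
#'
#' Latent progression and death times are exponential at the configured
#' medians, conditioned to be compatible with each patient's drawn
#' objective-response and DCB indicators (a responder's progression and
#' death fall beyond the confirming CT; a DCB patient's beyond the fourth
#' CT — the exponential's memorylessness makes the conditional draw an
#' offset draw). Progression is only observed at the next scheduled CT;
#' death is observed exactly. Deterministic given `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return List of [patient_record] objects.
#' @export
generate_patients <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  ct <- cfg$ct_interval_days
  day4 <- 4L * ct
  min_days <- 154L
  confirm_day <- 2L * ct
  patients <- list()
  for (label in names(cfg$cohort_sizes)) {
    n <- cfg$cohort_sizes[[label]]
    if (n == 0L) next
    r_pfs <- log(2) / (cfg$pfs_median_months[[label]] * DAYS_PER_MONTH)
    r_os <- log(2) / (cfg$os_median_months[[label]] * DAYS_PER_MONTH)
    r_drop <- log(2) / (cfg$dropout_median_months * DAYS_PER_MONTH)
    for (i in seq_len(n)) {
      per_protocol <- runif(1) > cfg$per_protocol_exclusion_prob
      or_ind <- runif(1) < cfg$true_or_rate[[label]]
      dcb_ind <- runif(1) < cfg$true_dcb_rate[[label]]

      tp <- if (dcb_ind) day4 + rexp(1, r_pfs)
            else if (or_ind) rexp_trunc(r_pfs, confirm_day + 1, min_days - 1)
            else rexp_trunc(r_pfs, 1, min_days - 1)
      td <- if (dcb_ind) day4 + 7 + rexp(1, r_os)
            else if (or_ind) confirm_day + 1 + rexp(1, r_os)
            else 1 + rexp(1, r_os)
      tc <- rexp(1, r_drop)
      follow_end <- min(td, tc)

      # scheduled scans strictly before progression and end of follow-up
      grid <- seq(ct, by = ct, length.out = 30L)
      scan_days <- grid[grid < min(tp, follow_end)]
      pd_ct <- grid[grid >= tp][1L]
      has_pd <- !is.na(pd_ct) && pd_ct < follow_end

      base_sum <- round(runif(1, 30, 120), 1)
      shrink <- runif(1, 0.35, 0.60)
      n_scan <- length(scan_days)
      recist <- character(n_scan)
      sums <- numeric(n_scan)
      for (k in seq_len(n_scan)) {
        if (or_ind) {
          recist[k] <- "PR"
          sums[k] <- round(base_sum * (1 - shrink) * (1 + runif(1, -0.03, 0.03)), 1)
        } else if (runif(1) < 0.03) {
          recist[k] <- "NE"
          sums[k] <- NA_real_
        } else {
          recist[k] <- "SD"
          sums[k] <- round(base_sum * (1 + runif(1, -0.15, 0.15)), 1)
        }
      }
      assessments <- data.frame(day = as.integer(scan_days), recist = recist,
                                target_sum_mm = sums, stringsAsFactors = FALSE)
      progression_day <- NA_integer_
      if (has_pd) {
        assessments <- rbind(assessments, data.frame(
          day = as.integer(pd_ct), recist = "PD",
          target_sum_mm = round(base_sum * (1 + runif(1, 0.25, 0.60)), 1)))
        progression_day <- as.integer(pd_ct)
      }

      os_event <- td <= tc
      os_days <- max(1L, as.integer(ceiling(follow_end)))
      treat_end <- min(tp, follow_end)
      cycles <- min(17L, max(1L, as.integer(ceiling(treat_end / cfg$cycle_days))))

      patients[[length(patients) + 1L]] <- patient_record(
        patient_id = sprintf("%s-%03d", label, i),
        cohort = label,
        per_protocol = per_protocol,
        assessments = assessments,
        baseline_target_sum_mm = base_sum,
        os_days = os_days,
        os_event = os_event,
        progression_day = progression_day,
        last_contact_day = os_days,
        cycles_received = cycles
      )
    }
  }
  patients
}

#' Generate synthetic ctDNA variants and a plasma-sample inventory
#'
#' Per patient-timepoint, sample sufficiency is drawn with
#' `insufficient_dna_prob` (emulating <9 ng dropouts). Per gene, detection is
#' drawn at `baseline_detect_prob`, with post-treatment odds multiplied by
#' `post_odds_multiplier`. Each detected gene in a sufficient sample emits
#' 1-2 variant rows whose classifications satisfy [is_pathogenic()].
#' Uses the seed sub-stream `cfg$seed + 1`.
#'
#' @param cfg A [generator_config()].
#' @param patients Patient list from [generate_patients()]; the ctDNA frame
#'   is the per-protocol population.
#' @return List with elements `variants` (a `"variant_calls"` data frame)
#'   and `inventory` (a `"sample_inventory"` data frame).
#' @export
generate_ctdna <- function(cfg, patients) {
  set.seed(cfg$seed + 1L)
  frame <- Filter(function(p) p$per_protocol, patients)
  inv_rows <- list()
  var_rows <- list()
  for (p in frame) {
    for (tp in TIMEPOINT_LEVELS) {
      sufficient <- runif(1) >= cfg$insufficient_dna_prob
      dna_ng <- if (sufficient) round(runif(1, 9, 75), 1) else round(runif(1, 0.5, 8.9), 1)
      inv_rows[[length(inv_rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, timepoint = tp, dna_ng = dna_ng,
        stringsAsFactors = FALSE)
      if (!sufficient) next
      for (g in cfg$gene_panel) {
        pr <- cfg$baseline_detect_prob[[g]]
        if (tp == "post") {
          odds <- pr / (1 - pr) * cfg$post_odds_multiplier[[g]]
          pr <- odds / (1 + odds)
        }
        if (runif(1) >= pr) next
        for (v in seq_len(sample(1:2, 1))) {
          kind <- sample(c("frameshift", "missense", "splice", "inframe_indel"), 1,
                         prob = c(0.4, 0.35, 0.1, 0.15))
          var_rows[[length(var_rows) + 1L]] <- data.frame(
            patient_id = p$patient_id, timepoint = tp, gene = g,
            classification = kind,
            indel_length_nt = if (kind == "inframe_indel") 3L else NA_integer_,
            splice_pathogenic = if (kind == "splice") TRUE else NA,
            cadd = if (kind == "missense") round(runif(1, 20.5, 40), 1) else NA_real_,
            vaf = round(runif(1, 0.005, 0.30), 4),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  inventory <- if (length(inv_rows)) do.call(rbind, inv_rows) else
    data.frame(patient_id = character(), timepoint = character(),
               dna_ng = numeric(), stringsAsFactors = FALSE)
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(patient_id = character(), timepoint = character(),
               gene = character(), classification = character(),
               indel_length_nt = integer(), splice_pathogenic = logical(),
               cadd = numeric(), vaf = numeric(), stringsAsFactors = FALSE)
  list(variants = validate_variants(variants),
       inventory = validate_samples(inventory))
}
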