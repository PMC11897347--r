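# Fixture builders used across the suite. Everything is constructed in code;
# no data files.

# A patient with sensible defaults, overridable per test.
make_patient <- function(patient_id = "P01", cohort = "B2D",
                         per_protocol = TRUE,
                         days = c(42, 84), recist = c("SD", "SD"),
                         sums = NA_real_,
                         baseline = 100,
                         os_days = max(c(days, 200)), os_event = FALSE,
                         progression_day = NA, last_contact_day = os_days,
                         cycles = 2) {
  assessments <- if (length(days) == 0) {
    data.frame(day = integer(), recist = character(), target_sum_mm = numeric())
  } else {
    data.frame(day = days, recist = recist,
               target_sum_mm = rep_len(sums, length(days)))
  }
  patient_record(patient_id, cohort, per_protocol = per_protocol,
                 assessments = assessments,
                 baseline_target_sum_mm = baseline,
                 os_days = os_days, os_event = os_event,
                 progression_day = progression_day,
                 last_contact_day = last_contact_day,
                 cycles_received = cycles)
}

# A 26-patient per-protocol cohort built to carry 2 confirmed responders and
# 6 patients with durable clinical benefit (responders included), the rest
# progressing early.
b2d_fixture <- function(cohort = "B2D") {
  patients <- list()
  id <- 0
  nxt <- function() {
    id <<- id + 1
    sprintf("%s-%02d", cohort, id)
  }
  # 2 confirmed responders, progression-free through the 4th CT
  for (i in 1:2) {
    patients[[length(patients) + 1]] <- make_patient(
      nxt(), cohort,
      days = c(42, 84, 126, 168, 210),
      recist = c("PR", "PR", "PR", "PR", "PD"),
      sums = c(60, 55, 52, 52, 90),
      os_days = 400, os_event = TRUE, progression_day = 210)
  }
  # 4 further DCB patients: stable through the 4th CT, progress later
  for (i in 1:4) {
    patients[[length(patients) + 1]] <- make_patient(
      nxt(), cohort,
      days = c(42, 84, 126, 168, 210),
      recist = c("SD", "SD", "SD", "SD", "PD"),
      sums = c(95, 97, 96, 98, 130),
      os_days = 300, os_event = TRUE, progression_day = 210)
  }
  # 20 early progressors
  for (i in 1:20) {
    patients[[length(patients) + 1]] <- make_patient(
      nxt(), cohort,
      days = c(42, 84), recist = c("SD", "PD"), sums = c(105, 130),
      os_days = 180, os_event = TRUE, progression_day = 84)
  }
  patients
}

# A 17-patient cohort with 2 DCB patients (no responders).
b2s_fixture <- function() {
  patients <- b2d_fixture(cohort = "B2S")[7:21]  # 15 early progressors + 0 DCB
  # relabel to keep ids unique and add the 2 DCB patients
  patients <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    p$patient_id <- sprintf("B2S-%02d", i)
    p$cohort <- "B2S"
    p
  })
  for (i in 16:17) {
    patients[[length(patients) + 1]] <- make_patient(
      sprintf("B2S-%02d", i), "B2S",
      days = c(42, 84, 126, 168, 210),
      recist = c("SD", "SD", "SD", "SD", "PD"),
      sums = c(95, 97, 96, 98, 130),
      os_days = 300, os_event = TRUE, progression_day = 210)
  }
  patients
}

# A variant-call data frame row.
make_variant <- function(patient_id, timepoint, gene,
                         classification = "frameshift",
                         indel_length_nt = NA_integer_,
                         splice_pathogenic = NA, cadd = NA_real_,
                         vaf = 0.05) {
  trialscreen:::validate_variants(data.frame(
    patient_id = patient_id, timepoint = timepoint, gene = gene,
    classification = classification,
    indel_length_nt = as.integer(indel_length_nt),
    splice_pathogenic = splice_pathogenic,
    cadd = cadd, vaf = vaf, stringsAsFactors = FALSE))
}

# Sample inventory covering n_baseline + n_post sufficient samples (patients
# B01.., P01..), plus optional insufficient ones.
make_inventory <- function(n_baseline, n_post, extra = NULL) {
  rows <- rbind(
    if (n_baseline > 0)
      data.frame(patient_id = sprintf("PT%02d", seq_len(n_baseline)),
                 timepoint = "baseline", dna_ng = 20),
    if (n_post > 0)
      data.frame(patient_id = sprintf("PT%02d", seq_len(n_post)),
                 timepoint = "post", dna_ng = 20),
    extra)
  trialscreen:::validate_samples(rows)
}

# Detectability fixture calibrated to the reported counts: one enriched gene
# at 3/36 vs 11/27, one at 0/36 vs 4/27, and `n_null` null genes detected in
# 2 patients at both timepoints.
calibrated_ctdna_fixture <- function(n_null = 20) {
  variants <- list()
  add <- function(patients, timepoint, gene) {
    for (p in patients)
      variants[[length(variants) + 1]] <<- data.frame(
        patient_id = p, timepoint = timepoint, gene = gene,
        classification = "frameshift", indel_length_nt = NA_integer_,
        splice_pathogenic = NA, cadd = NA_real_, vaf = 0.05,
        stringsAsFactors = FALSE)
  }
  # baseline frame PT01..PT36 sufficient; post frame PT01..PT27 sufficient
  add(sprintf("PT%02d", 1:3), "baseline", "GENE_A")
  add(sprintf("PT%02d", 1:11), "post", "GENE_A")
  add(sprintf("PT%02d", 5:8), "post", "GENE_B")
  null_genes <- sprintf("NULL%02d", seq_len(n_null))
  for (g in null_genes) {
    add(sprintf("PT%02d", 12:13), "baseline", g)
    add(sprintf("PT%02d", 12:13), "post", g)
  }
  inventory <- make_inventory(36, 27)
  list(variants = trialscreen:::validate_variants(do.call(rbind, variants)),
       inventory = inventory,
       genes = c("GENE_A", "GENE_B", null_genes))
}

# Independent oracle for the two-sided exact test: explicit enumeration of
# admissible tables with fixed margins, point probabilities from choose().
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; nw <- b + d; k <- a + b
  support <- max(0, k - nw):min(k, m)
  prob <- choose(m, support) * choose(nw, k - support) / choose(m + nw, k)
  p_obs <- choose(m, a) * choose(nw, k - a) / choose(m + nw, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}
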