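# Domain types and delimited-text IO for the trial data model.
#
# Times are integer day offsets from treatment start (day 0 = first dose);
# calendar dates are out of scope. Missing numeric fields are empty cells,
# never sentinel numbers.

RECIST_LEVELS <- c("CR", "PR", "SD", "PD", "NE")
TIMEPOINT_LEVELS <- c("baseline", "post")
CLASSIFICATION_LEVELS <- c("frameshift", "inframe_indel", "splice", "missense",
                           "nonsense", "synonymous", "other")

#' Construct a validated patient record
#'
#' A patient record bundles the per-patient fields of the trial table: cohort
#' label, analysis-population flag, the ordered series of CT assessments, and
#' survival/censoring fields. All invariants are checked at construction.
#'
#' @param patient_id Non-empty string.
#' @param cohort Cohort label (e.g. `"B1"`, `"B2D"`, `"B2S"`; arbitrary
#'   non-empty labels are preserved verbatim).
#' @param per_protocol Logical; `TRUE` if the patient belongs to the
#'   per-protocol efficacy population.
#' @param assessments Data frame with columns `day` (integer days since
#'   treatment start, >= 0), `recist` (one of CR, PR, SD, PD, NE) and
#'   `target_sum_mm` (non-negative target-lesion diameter sum, or `NA`).
#'   Rows are sorted by `day`; duplicate days are an error.
#' @param baseline_target_sum_mm Baseline target-lesion sum in mm, or `NA`.
#' @param os_days Positive integer: days from treatment start to death or
#'   last follow-up. Must be >= the last assessment day.
#' @param os_event Logical; `TRUE` if the patient died at `os_days`.
#' @param progression_day Integer day of documented progression, or `NA`.
#'   When present must be <= `os_days`.
#' @param last_contact_day Integer day of last contact (censoring time for
#'   time-to-event endpoints without an event).
#' @param cycles_received Non-negative integer count of 28-day treatment
#'   cycles started.
#'
#' @return A list of class `"patient_record"`.
#' @export
#' @examples
#' p <- patient_record("P01", "B2D",
#'   assessments = data.frame(day = c(42, 84), recist = c("PR", "PR"),
#'                            target_sum_mm = c(52, 50)),
#'   baseline_target_sum_mm = 100, os_days = 200, os_event = TRUE,
#'   progression_day = 120, last_contact_day = 200)
patient_record <- function(patient_id, cohort, per_protocol = TRUE,
                           assessments = empty_assessments(),
                           baseline_target_sum_mm = NA_real_,
                           os_days, os_event,
                           progression_day = NA_integer_,
                           last_contact_day, cycles_received = 0L) {
  stop_if(!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id),
          "patient_id must be a non-empty string")
  stop_if(!is.character(cohort) || length(cohort) != 1L || !nzchar(cohort),
          "cohort label must be a non-empty string [patient %s]", patient_id)
  assessments <- validate_assessments(assessments, patient_id)
  os_days <- as.integer(os_days)
  stop_if(is.na(os_days) || os_days <= 0L,
          "os_days must be a positive integer [patient %s]", patient_id)
  if (nrow(assessments) > 0L)
    stop_if(os_days < max(assessments$day),
            "os_days (%d) earlier than last assessment day (%d) [patient %s]",
            os_days, max(assessments$day), patient_id)
  progression_day <- as.integer(progression_day)
  if (!is.na(progression_day))
    stop_if(progression_day > os_days,
            "progression_day (%d) after os_days (%d) [patient %s]",
            progression_day, os_days, patient_id)
  stop_if(!is.na(baseline_target_sum_mm) && baseline_target_sum_mm < 0,
          "baseline_target_sum_mm must be non-negative [patient %s]", patient_id)
  structure(list(
    patient_id = patient_id,
    cohort = cohort,
    per_protocol = isTRUE(per_protocol),
    baseline_target_sum_mm = as.numeric(baseline_target_sum_mm),
    assessments = assessments,
    os_days = os_days,
    os_event = isTRUE(os_event),
    progression_day = progression_day,
    last_contact_day = as.integer(last_contact_day),
    cycles_received = as.integer(cycles_received)
  ), class = "patient_record")
}

empty_assessments <- function() {
  data.frame(day = integer(), recist = character(),
             target_sum_mm = numeric(), stringsAsFactors = FALSE)
}

validate_assessments <- function(a, patient_id = "?") {
  stop_if(!is.data.frame(a) || !all(c("day", "recist") %in% names(a)),
          "assessments must be a data frame with columns day, recist [patient %s]",
          patient_id)
  if (is.null(a$target_sum_mm)) a$target_sum_mm <- NA_real_
  a <- a[, c("day", "recist", "target_sum_mm")]
  a$day <- as.integer(a$day)
  a$recist <- as.character(a$recist)
  a$target_sum_mm <- as.numeric(a$target_sum_mm)
  stop_if(anyNA(a$day) || any(a$day < 0L),
          "assessment day must be a non-negative integer [patient %s]", patient_id)
  bad <- setdiff(unique(a$recist), RECIST_LEVELS)
  stop_if(length(bad) > 0L, "unknown RECIST category '%s' [patient %s]",
          bad[1L], patient_id)
  stop_if(any(!is.na(a$target_sum_mm) & a$target_sum_mm < 0),
          "target_sum_mm must be non-negative [patient %s]", patient_id)
  stop_if(anyDuplicated(a$day) > 0L,
          "duplicate assessment day %d [patient %s]",
          a$day[anyDuplicated(a$day)], patient_id)
  a <- a[order(a$day), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s  cohort %s  %s\n", x$patient_id, x$cohort,
              if (x$per_protocol) "per-protocol" else "excluded"))
  cat(sprintf("  %d assessment(s); OS %d d (%s); progression %s\n",
              nrow(x$assessments), x$os_days,
              if (x$os_event) "death" else "censored",
              if (is.na(x$progression_day)) "none" else
                sprintf("day %d", x$progression_day)))
  invisible(x)
}

stop_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

# ---- patients.csv ---------------------------------------------------------

PATIENT_COLUMNS <- c("patient_id", "cohort", "per_protocol",
                     "baseline_target_sum_mm", "os_days", "os_event",
                     "progression_day", "last_contact_day", "cycles_received",
                     "assessment_day", "recist", "target_sum_mm")

#' Read a patient-level trial table
#'
#' Reads the long ("one row per assessment") patient dialect: patient-level
#' fields are repeated on every row of a patient, assessment fields
#' (`assessment_day`, `recist`, `target_sum_mm`) vary by row. A patient with
#' no assessments occupies a single row with the assessment fields blank.
#' All type invariants are enforced; records are returned sorted by
#' `patient_id` with assessments sorted by day.
#'
#' @param path Path to a delimited text file with header
#'   `r paste(PATIENT_COLUMNS, collapse = ",")`.
#' @param sep Field separator (default `","`).
#' @return A list of [patient_record] objects, ordered by `patient_id`.
#' @seealso [write_patients()] for the inverse operation.
#' @export
read_patients <- function(path, sep = ",") {
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  stringsAsFactors = FALSE)
  missing_cols <- setdiff(PATIENT_COLUMNS, names(raw))
  stop_if(length(missing_cols) > 0L, "patients file %s lacks column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) return(list())

  num_field <- function(v, row, field) {
    v <- trimws(v)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(nzchar(v) & is.na(out))
    stop_if(length(bad) > 0L, "row %d: field '%s' is not numeric ('%s')",
            row[bad[1L]], field, v[bad[1L]])
    out
  }
  bool_field <- function(v, row, field) {
    v <- toupper(trimws(v))
    out <- ifelse(v %in% c("TRUE", "T", "1"), TRUE,
                  ifelse(v %in% c("FALSE", "F", "0"), FALSE, NA))
    bad <- which(is.na(out))
    stop_if(length(bad) > 0L, "row %d: field '%s' is not logical ('%s')",
            row[bad[1L]], field, v[bad[1L]])
    out
  }

  rows <- seq_len(nrow(raw)) + 1L  # +1 for the header line
  raw$patient_id <- trimws(raw$patient_id)
  stop_if(any(!nzchar(raw$patient_id)), "row %d: field 'patient_id' is empty",
          rows[which(!nzchar(raw$patient_id))[1L]])
  dup_key <- paste(raw$patient_id, trimws(raw$assessment_day))
  has_assess <- nzchar(trimws(raw$assessment_day))
  dup <- duplicated(dup_key) & has_assess
  stop_if(any(dup), "row %d: duplicate assessment for (%s, day %s)",
          rows[which(dup)[1L]], raw$patient_id[which(dup)[1L]],
          trimws(raw$assessment_day)[which(dup)[1L]])

  patients <- lapply(split(seq_len(nrow(raw)), raw$patient_id), function(idx) {
    first <- idx[1L]
    r <- rows[idx]
    keep <- idx[nzchar(trimws(raw$assessment_day[idx]))]
    assessments <- if (length(keep) == 0L) empty_assessments() else
      data.frame(day = num_field(raw$assessment_day[keep], rows[keep], "assessment_day"),
                 recist = trimws(raw$recist[keep]),
                 target_sum_mm = num_field(raw$target_sum_mm[keep], rows[keep],
                                           "target_sum_mm"),
                 stringsAsFactors = FALSE)
    patient_record(
      patient_id = raw$patient_id[first],
      cohort = trimws(raw$cohort[first]),
      per_protocol = bool_field(raw$per_protocol[first], r[1L], "per_protocol"),
      assessments = assessments,
      baseline_target_sum_mm = num_field(raw$baseline_target_sum_mm[first],
                                         r[1L], "baseline_target_sum_mm"),
      os_days = num_field(raw$os_days[first], r[1L], "os_days"),
      os_event = bool_field(raw$os_event[first], r[1L], "os_event"),
      progression_day = num_field(raw$progression_day[first], r[1L],
                                  "progression_day"),
      last_contact_day = num_field(raw$last_contact_day[first], r[1L],
                                   "last_contact_day"),
      cycles_received = num_field(raw$cycles_received[first], r[1L],
                                  "cycles_received")
    )
  })
  unname(patients[order(names(patients))])
}

#' Write patient records to the long patients dialect
#'
#' Inverse of [read_patients()]: writing then reading reproduces the records
#' exactly, and repeated writes of the same records are byte-identical.
#'
#' @param patients List of [patient_record] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  rows <- lapply(patients, function(p) {
    a <- p$assessments
    n <- max(1L, nrow(a))
    data.frame(
      patient_id = rep(p$patient_id, n),
      cohort = rep(p$cohort, n),
      per_protocol = rep(p$per_protocol, n),
      baseline_target_sum_mm = rep(p$baseline_target_sum_mm, n),
      os_days = rep(p$os_days, n),
      os_event = rep(p$os_event, n),
      progression_day = rep(p$progression_day, n),
      last_contact_day = rep(p$last_contact_day, n),
      cycles_received = rep(p$cycles_received, n),
      assessment_day = if (nrow(a)) a$day else NA_integer_,
      recist = if (nrow(a)) a$recist else NA_character_,
      target_sum_mm = if (nrow(a)) a$target_sum_mm else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    writeLines(paste(PATIENT_COLUMNS, collapse = ","), path)
    return(invisible(path))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$assessment_day), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- variants.tsv (MAF-like) ----------------------------------------------

#' Default MAF-vocabulary to internal classification mapping
#'
#' Maps (case-insensitively) the common MAF `Variant_Classification` terms to
#' the internal enumeration used by [is_pathogenic()]. The same table ships
#' as `inst/extdata/classification_map.yaml`; pass a modified copy to
#' [read_variants()] to change the mapping without touching code.
#'
#' @return Named character vector: names are MAF terms (lower case), values
#'   are internal classifications.
#' @export
maf_classification_map <- function() {
  path <- system.file("extdata", "classification_map.yaml",
                      package = "trialscreen")
  if (nzchar(path)) {
    m <- unlist(yaml::read_yaml(path))
    return(setNames(as.character(m), tolower(names(m))))
  }
  # fallback when called from a source checkout
  c(frame_shift_del = "frameshift", frame_shift_ins = "frameshift",
    in_frame_del = "inframe_indel", in_frame_ins = "inframe_indel",
    splice_site = "splice", splice_region = "splice",
    missense_mutation = "missense", nonsense_mutation = "nonsense",
    nonstop_mutation = "nonsense", silent = "synonymous",
    synonymous = "synonymous")
}

#' Read a MAF-like ctDNA variant table
#'
#' Expects a delimited file with columns `patient_id`, `timepoint`
#' (`baseline`/`post`), `Hugo_Symbol`, `Variant_Classification`, and the
#' optional annotation columns `indel_length_nt`, `splice_pathogenic`,
#' `CADD`, `VAF` (blank = missing). Classification strings are normalised
#' case-insensitively through `class_map`; unknown terms map to `"other"`
#' with a warning, never an error. Duplicate patient/gene/timepoint rows are
#' preserved — deduplication happens in [build_detectability()].
#'
#' @param path Path to the variants file.
#' @param sep Field separator (default tab).
#' @param class_map Named character vector as from [maf_classification_map()].
#' @return Data frame of class `"variant_calls"` with columns `patient_id`,
#'   `timepoint`, `gene`, `classification`, `indel_length_nt`,
#'   `splice_pathogenic`, `cadd`, `vaf`.
#' @export
read_variants <- function(path, sep = "\t",
                          class_map = maf_classification_map()) {
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "timepoint", "Hugo_Symbol", "Variant_Classification")
  missing_cols <- setdiff(need, names(raw))
  stop_if(length(missing_cols) > 0L, "variants file %s lacks column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  opt <- function(col) if (col %in% names(raw)) trimws(raw[[col]]) else
    rep("", nrow(raw))
  num_or_na <- function(v) suppressWarnings(as.numeric(ifelse(nzchar(v), v, NA)))
  lgl_or_na <- function(v) {
    v <- toupper(v)
    ifelse(v %in% c("TRUE", "T", "1"), TRUE,
           ifelse(v %in% c("FALSE", "F", "0"), FALSE, NA))
  }

  cls_orig <- trimws(raw$Variant_Classification)
  cls <- unname(class_map[tolower(cls_orig)])
  unknown <- is.na(cls) & nzchar(cls_orig)
  if (any(unknown))
    warning(sprintf("unknown variant classification(s) mapped to 'other': %s",
                    paste(unique(cls_orig[unknown]), collapse = ", ")),
            call. = FALSE)
  cls[is.na(cls)] <- "other"

  out <- data.frame(
    patient_id = trimws(raw$patient_id),
    timepoint = tolower(trimws(raw$timepoint)),
    gene = toupper(trimws(raw$Hugo_Symbol)),
    classification = cls,
    indel_length_nt = as.integer(num_or_na(opt("indel_length_nt"))),
    splice_pathogenic = lgl_or_na(opt("splice_pathogenic")),
    cadd = num_or_na(opt("CADD")),
    vaf = num_or_na(opt("VAF")),
    stringsAsFactors = FALSE
  )
  validate_variants(out)
}

validate_variants <- function(v) {
  stop_if(any(!nzchar(v$gene)), "gene symbol must be non-empty")
  bad_tp <- setdiff(unique(v$timepoint), TIMEPOINT_LEVELS)
  stop_if(length(bad_tp) > 0L, "unknown timepoint '%s'", bad_tp[1L])
  bad_cls <- setdiff(unique(v$classification), CLASSIFICATION_LEVELS)
  stop_if(length(bad_cls) > 0L, "unknown classification '%s'", bad_cls[1L])
  stop_if(any(!is.na(v$cadd) & v$cadd < 0), "CADD scores must be non-negative")
  stop_if(any(!is.na(v$vaf) & (v$vaf < 0 | v$vaf > 1)), "VAF must lie in [0,1]")
  class(v) <- c("variant_calls", "data.frame")
  v
}

#' Write a variant table in the MAF-like dialect read by [read_variants()]
#'
#' @param variants `"variant_calls"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  out <- data.frame(
    patient_id = variants$patient_id,
    timepoint = variants$timepoint,
    Hugo_Symbol = variants$gene,
    Variant_Classification = variants$classification,
    indel_length_nt = variants$indel_length_nt,
    splice_pathogenic = variants$splice_pathogenic,
    CADD = variants$cadd,
    VAF = variants$vaf,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- samples.csv -----------------------------------------------------------

#' Read a plasma-sample inventory
#'
#' One row per patient-timepoint with the quantified cfDNA mass. A sample is
#' sufficient for sequencing when `dna_ng >= threshold_ng` (default 9 ng);
#' only sufficient samples contribute to enrichment denominators.
#'
#' @param path Path to a CSV with columns `patient_id`, `timepoint`, `dna_ng`.
#' @param threshold_ng Minimum DNA input judged sufficient (default 9).
#' @return Data frame of class `"sample_inventory"` with an added logical
#'   `sufficient` column.
#' @export
read_samples <- function(path, threshold_ng = 9) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "dna_ng")
  missing_cols <- setdiff(need, names(raw))
  stop_if(length(missing_cols) > 0L, "samples file %s lacks column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  out <- data.frame(
    patient_id = trimws(as.character(raw$patient_id)),
    timepoint = tolower(trimws(as.character(raw$timepoint))),
    dna_ng = as.numeric(raw$dna_ng),
    stringsAsFactors = FALSE
  )
  validate_samples(out, threshold_ng)
}

validate_samples <- function(s, threshold_ng = 9) {
  bad_tp <- setdiff(unique(s$timepoint), TIMEPOINT_LEVELS)
  stop_if(length(bad_tp) > 0L, "unknown timepoint '%s'", bad_tp[1L])
  stop_if(anyNA(s$dna_ng) || any(s$dna_ng < 0), "dna_ng must be non-negative")
  key <- paste(s$patient_id, s$timepoint)
  stop_if(anyDuplicated(key) > 0L, "duplicate sample for (%s)",
          key[anyDuplicated(key)])
  s$sufficient <- s$dna_ng >= threshold_ng
  class(s) <- c("sample_inventory", "data.frame")
  s
}

#' Write a sample inventory CSV
#'
#' @param samples `"sample_inventory"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  out <- samples[, c("patient_id", "timepoint", "dna_ng")]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- result writing --------------------------------------------------------

#' Write named result tables to a directory
#'
#' Each table is written as `<name>.csv` with its column order preserved.
#' Re-running on identical input yields byte-identical files. A manifest of
#' files and row counts is returned and also written as `manifest.csv`.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if absent).
#' @return Data frame with columns `file` and `rows` (the manifest).
#' @export
write_results <- function(tables, path) {
  stop_if(is.null(names(tables)) || any(!nzchar(names(tables))),
          "tables must be a named list")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(path), "cannot create output directory %s", path)
  files <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    write.csv(tables[[nm]], f, row.names = FALSE, na = "")
    files <- c(files, basename(f))
    rows <- c(rows, nrow(tables[[nm]]))
  }
  manifest <- data.frame(file = files, rows = rows, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(path, "manifest.csv"), row.names = FALSE)
  manifest
}
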