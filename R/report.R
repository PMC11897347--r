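# End-to-end pipeline commands and run manifests. These are the package's
# batch entry points: each generates or consumes the delimited-text dialects
# of the data model, writes result tables with stable column order, and
# records a run manifest (command, config hash, seed, inputs, outputs).

#' Format a p-value the way the report prints it
#'
#' Three decimal places, with a floor shown as `"<0.001"`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass_recursive(config), f)
  unname(tools::md5sum(f))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

write_run_manifest <- function(out_dir, command, config, seed, inputs, outputs) {
  manifest <- list(command = command,
                   config_hash = config_hash(config),
                   seed = if (is.null(seed)) NA else seed,
                   input_paths = as.list(inputs),
                   output_paths = as.list(outputs),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  manifest
}

#' Simulate a synthetic trial and write its data files
#'
#' Generates the patient cohort and the ctDNA tables from a
#' [generator_config()] and writes `patients.csv`, `variants.tsv`,
#' `samples.csv` and a run manifest to `out_dir`. Repeating the run with the
#' same seed writes identical data files.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `patients`, `variants`, `inventory`,
#'   `manifest`.
#' @export
run_simulate <- function(cfg = generator_config(), out_dir) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(out_dir), "cannot create output directory %s", out_dir)
  patients <- generate_patients(cfg)
  ctdna <- generate_ctdna(cfg, patients)
  paths <- file.path(out_dir, c("patients.csv", "variants.tsv", "samples.csv"))
  write_patients(patients, paths[1L])
  write_variants(ctdna$variants, paths[2L])
  write_samples(ctdna$inventory, paths[3L])
  manifest <- write_run_manifest(out_dir, "simulate", cfg, cfg$seed,
                                 character(0), paths)
  invisible(list(patients = patients, variants = ctdna$variants,
                 inventory = ctdna$inventory, manifest = manifest))
}

#' Run the screening analysis and write its report tables
#'
#' Fits [trial_screen()] and writes the per-patient endpoint table, the
#' posterior summary table (one row per cohort x endpoint with counts,
#' formatted estimate, exceedance probability and GO/NO-GO decision), the
#' survival table, waterfall export data, and a run manifest. All numeric
#' formatting is centralised: percents to 1 decimal, probabilities to 2,
#' p-values to 3.
#'
#' @param patients List of [patient_record] objects, or a path to a
#'   `patients.csv` in the [read_patients()] dialect.
#' @param config A [screen_config()] or a path to a YAML config.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Invisibly, a list with the fitted `"trial_screen"` (`fit`), the
#'   result `tables`, and the `manifest` (`NULL` when `out_dir` is `NULL`).
#' @export
run_analyze <- function(patients, config = screen_config(), out_dir = NULL) {
  input_paths <- character(0)
  if (is.character(patients)) {
    input_paths <- patients
    patients <- read_patients(patients)
  }
  if (is.character(config)) {
    input_paths <- c(input_paths, config)
    config <- read_config(config)
  }
  fit <- trial_screen(patients, config)
  r <- fit$rates
  summary_tab <- data.frame(
    cohort = r$cohort, endpoint = r$endpoint,
    successes = r$successes, n = r$n,
    estimate_pct = sprintf("%.1f", 100 * r$point),
    ci_low_pct = sprintf("%.1f", 100 * r$ci_low),
    ci_high_pct = sprintf("%.1f", 100 * r$ci_high),
    prob_exceeds = sprintf("%.2f", r$prob_exceeds),
    threshold = r$threshold,
    decision = r$decision,
    stringsAsFactors = FALSE)
  e <- fit$endpoints
  waterfall <- e[order(-e$best_pct_change),
                 c("patient_id", "cohort", "per_protocol", "best_pct_change")]
  tables <- list(endpoints = fit$endpoints,
                 posterior_summary = summary_tab,
                 survival = fit$survival,
                 waterfall = waterfall)
  manifest <- NULL
  if (!is.null(out_dir)) {
    files <- write_results(tables, out_dir)
    manifest <- write_run_manifest(out_dir, "analyze", config, NULL,
                                   input_paths, file.path(out_dir, files$file))
  }
  invisible(list(fit = fit, tables = tables, manifest = manifest))
}

#' Run the ctDNA enrichment analysis and write its table
#'
#' Builds per-patient gene detectability from variants and the sample
#' inventory, runs the per-gene exact enrichment scan, and writes
#' `enrichment.tsv` (gene, 2x2 counts, p-value, significance flag, BH
#' q-value) plus a run manifest.
#'
#' @param variants A `"variant_calls"` data frame or a path to a
#'   `variants.tsv`.
#' @param samples A `"sample_inventory"` data frame or a path to a
#'   `samples.csv`.
#' @param genes Optional gene panel for the scan (default: genes observed).
#' @param config A [screen_config()] (used for the config hash only).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param alpha Significance level (default 0.05).
#' @return Invisibly, a list with the `"enrichment_table"` (`enrichment`),
#'   the `detectability` matrix, and the `manifest`.
#' @export
run_enrich <- function(variants, samples, genes = NULL,
                       config = screen_config(), out_dir = NULL,
                       alpha = 0.05) {
  input_paths <- character(0)
  if (is.character(variants)) {
    input_paths <- variants
    variants <- read_variants(variants)
  }
  if (is.character(samples)) {
    input_paths <- c(input_paths, samples)
    samples <- read_samples(samples)
  }
  detect <- build_detectability(variants, samples, genes = genes)
  enr <- enrichment_scan(detect, alpha = alpha)
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- enr
    out$p_value_fmt <- format_pvalue(out$p_value)
    f <- file.path(out_dir, "enrichment.tsv")
    write.table(out, f, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest <- write_run_manifest(out_dir, "enrich", config, NULL,
                                   input_paths, f)
  }
  invisible(list(enrichment = enr, detectability = detect, manifest = manifest))
}
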