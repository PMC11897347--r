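# Longitudinal ctDNA analysis: pathogenicity classification, per-patient
# gene detectability at baseline vs post-treatment, and per-gene exact
# enrichment tests.

#' Pathogenicity rule for a ctDNA variant
#'
#' A variant is pathogenic when it is a frameshift, OR an in-frame indel of
#' exactly 3 nt (a trinucleotide indel; set
#' `trinucleotide_rule = "divisible3"` to accept any in-frame length), OR a
#' splice variant annotated pathogenic, OR carries a CADD score strictly
#' above `cadd_cutoff`. Missing annotations simply fail their own clause.
#'
#' @param variants A `"variant_calls"` data frame (or any data frame with
#'   the same columns).
#' @param cadd_cutoff CADD deleteriousness threshold (default 20).
#' @param trinucleotide_rule `"exact3"` (default) or `"divisible3"`.
#' @return Logical vector, one element per variant row.
#' @export
is_pathogenic <- function(variants, cadd_cutoff = 20,
                          trinucleotide_rule = c("exact3", "divisible3")) {
  trinucleotide_rule <- match.arg(trinucleotide_rule)
  len_ok <- if (trinucleotide_rule == "exact3")
    !is.na(variants$indel_length_nt) & variants$indel_length_nt == 3L
  else
    !is.na(variants$indel_length_nt) & variants$indel_length_nt %% 3L == 0L
  frameshift <- variants$classification == "frameshift"
  tri_indel <- variants$classification == "inframe_indel" & len_ok
  path_splice <- variants$classification == "splice" &
    !is.na(variants$splice_pathogenic) & variants$splice_pathogenic
  high_cadd <- !is.na(variants$cadd) & variants$cadd > cadd_cutoff
  frameshift | tri_indel | path_splice | high_cadd
}

#' Per-patient gene detectability at baseline vs post-treatment
#'
#' A patient counts as detected for gene `g` at timepoint `t` when they carry
#' at least one pathogenic variant of `g` at `t` and their sample at `t` is
#' sufficient; multiple qualifying variants still count the patient once.
#' Denominators are the numbers of sufficient samples per timepoint.
#' Variants from insufficient samples are excluded with a warning.
#'
#' @param variants A `"variant_calls"` data frame.
#' @param inventory A `"sample_inventory"` data frame covering every
#'   patient-timepoint referenced by `variants`.
#' @param genes Genes to tabulate (default: all genes in `variants`).
#' @param cadd_cutoff,trinucleotide_rule Passed to [is_pathogenic()].
#' @return Object of class `"detectability_matrix"`: data frame with columns
#'   `gene`, `baseline_detected`, `post_detected` plus attributes
#'   `baseline_n`, `post_n`.
#' @export
build_detectability <- function(variants, inventory, genes = NULL,
                                cadd_cutoff = 20,
                                trinucleotide_rule = "exact3") {
  stopifnot(is.data.frame(variants), is.data.frame(inventory))
  inv_key <- paste(inventory$patient_id, inventory$timepoint)
  var_key <- paste(variants$patient_id, variants$timepoint)
  missing_inv <- setdiff(unique(var_key), inv_key)
  stop_if(length(missing_inv) > 0L,
          "no sample inventory entry for patient-timepoint(s): %s",
          paste(missing_inv, collapse = "; "))

  sufficient <- setNames(inventory$sufficient, inv_key)
  drop <- !sufficient[var_key]
  if (any(drop)) {
    warning(sprintf("%d variant(s) from insufficient samples excluded",
                    sum(drop)), call. = FALSE)
    variants <- variants[!drop, , drop = FALSE]
    var_key <- var_key[!drop]
  }

  if (is.null(genes)) genes <- sort(unique(variants$gene))
  baseline_n <- sum(inventory$sufficient[inventory$timepoint == "baseline"])
  post_n <- sum(inventory$sufficient[inventory$timepoint == "post"])

  path <- is_pathogenic(variants, cadd_cutoff, trinucleotide_rule)
  count_detected <- function(g, tp) {
    sel <- path & variants$gene == g & variants$timepoint == tp
    length(unique(variants$patient_id[sel]))
  }
  out <- data.frame(
    gene = genes,
    baseline_detected = vapply(genes, count_detected, integer(1), tp = "baseline"),
    post_detected = vapply(genes, count_detected, integer(1), tp = "post"),
    stringsAsFactors = FALSE
  )
  stop_if(any(out$baseline_detected > baseline_n) || any(out$post_detected > post_n),
          "detectability counts exceed denominators")
  rownames(out) <- NULL
  attr(out, "baseline_n") <- baseline_n
  attr(out, "post_n") <- post_n
  class(out) <- c("detectability_matrix", "data.frame")
  out
}

#' Two-sided Fisher exact test by the minimum-likelihood rule
#'
#' Exact conditional test on a 2x2 table with fixed margins: the two-sided
#' p-value is the sum of hypergeometric point probabilities of all admissible
#' tables whose probability does not exceed that of the observed table, the
#' comparison made with relative tolerance `1 + 1e-7` to absorb floating-point
#' ties. This is the common two-sided exact-test convention.
#'
#' @param a,b,c,d Cell counts: `a`/`b` detected/undetected at baseline,
#'   `c`/`d` detected/undetected post-treatment (any 2x2 layout works; the
#'   test is invariant under transposition).
#' @return The two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' fisher_two_sided(0, 36, 4, 23)   # 0.029
fisher_two_sided <- function(a, b, c, d) {
  stop_if(any(c(a, b, c, d) < 0), "cell counts must be non-negative")
  stop_if(a + b + c + d == 0, "empty table: the exact test is undefined")
  m <- a + c          # detected margin
  n_w <- b + d        # undetected margin
  k <- a + b          # baseline sample size
  support <- max(0L, k - n_w):min(k, m)
  probs <- dhyper(support, m, n_w, k)
  p_obs <- dhyper(a, m, n_w, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Per-gene enrichment scan of post-treatment vs baseline detectability
#'
#' Runs the two-sided exact test on every gene's 2x2 detectability table and
#' returns rows sorted by ascending p-value (ties broken by gene symbol).
#' Significance is flagged at `p < alpha` with no multiple-testing
#' correction; a Benjamini-Hochberg q-value column is emitted for
#' information only.
#'
#' @param matrix A `"detectability_matrix"` from [build_detectability()].
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `"enrichment_table"`: `gene`, `a`, `b`, `c`,
#'   `d` (baseline detected/undetected, post detected/undetected),
#'   `p_value`, `significant`, `q_value`.
#' @export
enrichment_scan <- function(matrix, alpha = 0.05) {
  stopifnot(inherits(matrix, "detectability_matrix"))
  baseline_n <- attr(matrix, "baseline_n")
  post_n <- attr(matrix, "post_n")
  stop_if(baseline_n + post_n == 0,
          "no sufficient samples at either timepoint: nothing to test")
  out <- data.frame(
    gene = matrix$gene,
    a = matrix$baseline_detected,
    b = baseline_n - matrix$baseline_detected,
    c = matrix$post_detected,
    d = post_n - matrix$post_detected,
    stringsAsFactors = FALSE
  )
  out$p_value <- mapply(fisher_two_sided, out$a, out$b, out$c, out$d)
  out$significant <- out$p_value < alpha
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
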