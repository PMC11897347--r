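test_that("the pathogenicity rule combines its four clauses correctly", {
  v <- make_variant("P1", "baseline", "SMARCA4", "frameshift")
  expect_true(is_pathogenic(v))                      # frameshift, CADD missing
  v <- make_variant("P1", "baseline", "TP53", "missense", cadd = 25)
  expect_true(is_pathogenic(v))                      # CADD > 20
  v <- make_variant("P1", "baseline", "TP53", "missense", cadd = 15)
  expect_false(is_pathogenic(v))
  v <- make_variant("P1", "baseline", "TP53", "missense", cadd = 20)
  expect_false(is_pathogenic(v))                     # strictly greater
  v <- make_variant("P1", "post", "SMARCA4", "inframe_indel",
                    indel_length_nt = 3)
  expect_true(is_pathogenic(v))                      # trinucleotide indel
  v6 <- make_variant("P1", "post", "SMARCA4", "inframe_indel",
                     indel_length_nt = 6)
  expect_false(is_pathogenic(v6))
  expect_true(is_pathogenic(v6, trinucleotide_rule = "divisible3"))
  v <- make_variant("P1", "post", "SMARCA4", "splice", splice_pathogenic = TRUE)
  expect_true(is_pathogenic(v))
  v <- make_variant("P1", "post", "SMARCA4", "splice")
  expect_false(is_pathogenic(v))                     # annotation missing
  v <- make_variant("P1", "post", "TP53", "synonymous")
  expect_false(is_pathogenic(v))
})

test_that("detectability counts patients once and respects sufficiency", {
  fx <- calibrated_ctdna_fixture(n_null = 0)
  d <- build_detectability(fx$variants, fx$inventory, genes = fx$genes)
  a_row <- d[d$gene == "GENE_A", ]
  expect_equal(c(a_row$baseline_detected, a_row$post_detected), c(3L, 11L))
  expect_equal(attr(d, "baseline_n"), 36L)
  expect_equal(attr(d, "post_n"), 27L)

  # two pathogenic variants of one gene in one patient count once
  v2 <- rbind(make_variant("PT01", "baseline", "G1", "frameshift"),
              make_variant("PT01", "baseline", "G1", "missense", cadd = 30))
  d <- build_detectability(trialscreen:::validate_variants(v2),
                           make_inventory(2, 2))
  expect_equal(d$baseline_detected[d$gene == "G1"], 1L)

  # gene absent from the variants gets a zero row
  d <- build_detectability(trialscreen:::validate_variants(v2),
                           make_inventory(2, 2), genes = c("G1", "G2"))
  expect_equal(d$baseline_detected[d$gene == "G2"], 0L)
  expect_equal(d$post_detected[d$gene == "G2"], 0L)

  # variants from insufficient samples are dropped with a warning
  inv <- make_inventory(1, 1, extra = data.frame(
    patient_id = "PT99", timepoint = "baseline", dna_ng = 5))
  v3 <- rbind(make_variant("PT01", "baseline", "G1", "frameshift"),
              make_variant("PT99", "baseline", "G1", "frameshift"))
  expect_warning(
    d <- build_detectability(trialscreen:::validate_variants(v3), inv),
    "insufficient")
  expect_equal(d$baseline_detected[d$gene == "G1"], 1L)

  # missing inventory is an error
  expect_error(build_detectability(make_variant("PX", "post", "G1"),
                                   make_inventory(1, 0)),
               "no sample inventory")
})

test_that("the two-sided exact test reproduces enumerated and library values", {
  expect_equal(round(fisher_two_sided(0, 36, 4, 23), 3), 0.029)
  expect_equal(fisher_two_sided(0, 36, 4, 23), 0.02946, tolerance = 1e-3)
  expect_equal(fisher_two_sided(3, 33, 11, 16), 0.00457, tolerance = 1e-3)
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1)
  # against the explicit enumeration oracle and stats::fisher.test
  set.seed(31)
  for (i in 1:50) {
    tab <- rbinom(4, size = 15, prob = 0.4)
    if (sum(tab) == 0) next
    p <- fisher_two_sided(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    expect_equal(p, fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
    expect_gt(p, 0)
    expect_lte(p, 1)
    # invariance under transposition and row/column swaps
    expect_equal(p, fisher_two_sided(tab[1], tab[3], tab[2], tab[4]),
                 tolerance = 1e-12)
    expect_equal(p, fisher_two_sided(tab[4], tab[3], tab[2], tab[1]),
                 tolerance = 1e-12)
  }
  expect_error(fisher_two_sided(0, 0, 0, 0), "empty table")
})

test_that("the enrichment scan flags exactly the enriched genes", {
  fx <- calibrated_ctdna_fixture(n_null = 20)
  d <- build_detectability(fx$variants, fx$inventory, genes = fx$genes)
  enr <- enrichment_scan(d)
  expect_equal(enr$gene[enr$significant], c("GENE_A", "GENE_B"))
  expect_equal(round(enr$p_value[enr$gene == "GENE_B"], 3), 0.029)
  # rows sorted ascending by p, ties broken by gene symbol
  expect_true(!is.unsorted(enr$p_value))
  expect_equal(enr$a + enr$b, rep(36L, nrow(enr)))
  expect_equal(enr$c + enr$d, rep(27L, nrow(enr)))

  # all-zero matrix: every p-value is 1
  empty <- build_detectability(
    trialscreen:::validate_variants(fx$variants[0, ]),
    fx$inventory, genes = c("G1", "G2"))
  expect_equal(enrichment_scan(empty)$p_value, c(1, 1))

  # permuting gene order does not change any p-value
  d_perm <- build_detectability(fx$variants, fx$inventory,
                                genes = rev(fx$genes))
  enr_perm <- enrichment_scan(d_perm)
  expect_equal(enr_perm[order(enr_perm$gene), "p_value"],
               enr[order(enr$gene), "p_value"])
})

test_that("the exact test is conservative under a simulated null", {
  # equal detection rates at both timepoints; two-sided exact p-values
  # should reject at most 5% of the time
  set.seed(77)
  n_rep <- 2000
  p_vals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rbinom(1, 36, 0.15)
    c_ <- rbinom(1, 27, 0.15)
    p_vals[i] <- fisher_two_sided(a, 36 - a, c_, 27 - c_)
  }
  expect_lte(mean(p_vals < 0.05), 0.05)
})
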