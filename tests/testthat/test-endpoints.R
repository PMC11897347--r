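test_that("confirmed objective response follows the RECIST confirmation rule", {
  expect_true(derive_objective_response(
    make_patient(days = c(42, 84), recist = c("PR", "PR"))))
  expect_false(derive_objective_response(
    make_patient(days = c(42, 84), recist = c("PR", "SD"))))
  # confirmation must be at least the window apart
  expect_false(derive_objective_response(
    make_patient(days = c(42, 60), recist = c("PR", "PR"))))
  expect_true(derive_objective_response(
    make_patient(days = c(42, 60), recist = c("PR", "PR")),
    confirm_window_days = 14))
  # intervening PD blocks confirmation
  expect_false(derive_objective_response(
    make_patient(days = c(42, 84, 126), recist = c("PR", "PD", "PR"),
                 progression_day = 84)))
  # empty series
  expect_false(derive_objective_response(
    make_patient(days = numeric(0), recist = character(0), sums = numeric(0))))
})

test_that("objective response is monotone: a later PD never creates one", {
  base_days <- c(42, 84, 126)
  for (rec in list(c("PR", "PR", "SD"), c("SD", "PR", "PR"), c("SD", "SD", "SD"))) {
    p <- make_patient(days = base_days, recist = rec)
    p_pd <- make_patient(days = c(base_days, 168), recist = c(rec, "PD"),
                         sums = rep(NA, 4), progression_day = 168)
    expect_gte(derive_objective_response(p),
               derive_objective_response(p_pd))
  }
})

test_that("durable clinical benefit needs a progression-free fourth CT past 22 weeks", {
  # PD at the second CT
  expect_false(derive_dcb(make_patient(days = c(42, 84), recist = c("SD", "PD"),
                                       progression_day = 84)))
  # four non-PD CTs, the fourth at day 161 >= 154
  expect_true(derive_dcb(make_patient(days = c(42, 84, 126, 161),
                                      recist = rep("SD", 4))))
  # three non-PD CTs then loss to follow-up at day 130: not evaluable
  expect_true(is.na(derive_dcb(make_patient(days = c(42, 84, 126),
                                            recist = rep("SD", 3),
                                            os_days = 130,
                                            last_contact_day = 130))))
  # death before the fourth CT
  expect_false(derive_dcb(make_patient(days = c(42, 84), recist = c("SD", "SD"),
                                       os_days = 100, os_event = TRUE,
                                       last_contact_day = 100)))
  # fourth CT too early, but a later progression-free CT past the threshold
  expect_true(derive_dcb(make_patient(days = c(30, 60, 90, 120, 160),
                                      recist = rep("SD", 5))))
  # progression after the qualifying CT does not retract the benefit
  expect_true(derive_dcb(make_patient(days = c(42, 84, 126, 168, 210),
                                      recist = c(rep("SD", 4), "PD"),
                                      progression_day = 210,
                                      os_days = 300)))
})

test_that("survival triple follows the stated censoring conventions", {
  s <- derive_survival(make_patient(progression_day = 60, os_days = 200,
                                    os_event = TRUE, days = c(42),
                                    recist = "SD"))
  expect_equal(s[c("pfs_days", "pfs_event", "ttp_days", "ttp_event",
                   "os_days", "os_event")],
               list(pfs_days = 60L, pfs_event = TRUE, ttp_days = 60L,
                    ttp_event = TRUE, os_days = 200L, os_event = TRUE))
  # death without progression: PFS event, TTP censored at death
  s <- derive_survival(make_patient(os_days = 90, os_event = TRUE,
                                    days = 42, recist = "SD",
                                    last_contact_day = 90))
  expect_true(s$pfs_event)
  expect_false(s$ttp_event)
  expect_equal(s$pfs_days, 90L)
  expect_equal(s$ttp_days, 90L)
  # alive without progression: everything censored at last contact
  s <- derive_survival(make_patient(os_days = 322, os_event = FALSE,
                                    days = 42, recist = "SD",
                                    last_contact_day = 322))
  expect_false(s$pfs_event)
  expect_false(s$ttp_event)
  expect_equal(c(s$pfs_days, s$ttp_days), c(322L, 322L))
})

test_that("best percent change follows the waterfall conventions", {
  expect_equal(best_pct_change(make_patient(days = c(42, 84),
                                            recist = c("PR", "PR"),
                                            sums = c(52, 60), baseline = 100)),
               -48)
  # no post-baseline measurement: the +100% default
  expect_equal(best_pct_change(make_patient(days = 42, recist = "NE",
                                            sums = NA)), 100)
  expect_equal(best_pct_change(make_patient(days = numeric(0),
                                            recist = character(0),
                                            sums = numeric(0))), 100)
  expect_equal(best_pct_change(make_patient(days = 42, recist = "SD",
                                            sums = 80, baseline = 80)), 0)
  expect_error(best_pct_change(make_patient(days = 42, recist = "SD",
                                            sums = 10, baseline = 0)),
               "zero")
  # invariance under uniform rescaling of all lesion sums
  p1 <- make_patient(days = c(42, 84), recist = c("SD", "SD"),
                     sums = c(90, 70), baseline = 100)
  p2 <- make_patient(days = c(42, 84), recist = c("SD", "SD"),
                     sums = c(90, 70) * 3.7, baseline = 370)
  expect_equal(best_pct_change(p1), best_pct_change(p2))
})

test_that("cohort counts reproduce the fixture's outcome profile", {
  patients <- c(b2d_fixture(), b2s_fixture())
  e <- derive_endpoints(patients)
  or_counts <- cohort_counts(e, "objective_response")
  expect_equal(or_counts[or_counts$cohort == "B2D", c("successes", "n")],
               data.frame(successes = 2L, n = 26L),
               ignore_attr = TRUE)
  dcb_counts <- cohort_counts(e, "dcb")
  expect_equal(dcb_counts[dcb_counts$cohort == "B2D", c("successes", "n")],
               data.frame(successes = 6L, n = 26L), ignore_attr = TRUE)
  expect_equal(dcb_counts[dcb_counts$cohort == "B2S", c("successes", "n")],
               data.frame(successes = 2L, n = 17L), ignore_attr = TRUE)
})

test_that("cohort counts handle empty sets and the conservative NA rule", {
  expect_equal(nrow(cohort_counts(derive_endpoints(list()), "dcb")), 0)
  # all not-evaluable: zero successes over the full denominator
  ne <- lapply(1:5, function(i)
    make_patient(sprintf("NE%02d", i), days = c(42, 84),
                 recist = c("SD", "SD"), os_days = 100,
                 last_contact_day = 100))
  e <- derive_endpoints(ne)
  expect_equal(cohort_counts(e, "dcb")$successes, 0L)
  expect_equal(cohort_counts(e, "dcb")$n, 5L)
  expect_equal(nrow(cohort_counts(e, "dcb", na_rule = "exclude")), 0L)
  expect_error(cohort_counts(e, "nonsense"))
})

test_that("derived endpoints satisfy the cross-endpoint invariants", {
  patients <- generate_patients(generator_config(seed = 11))
  e <- derive_endpoints(patients)
  dcb_true <- e[!is.na(e$dcb) & e$dcb, ]
  expect_true(all(dcb_true$pfs_days >= 154))
  expect_true(all(e$ttp_days == e$pfs_days))
  expect_true(all(!e$ttp_event | e$pfs_event))
  expect_true(all(e$best_pct_change >= -100))
})
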