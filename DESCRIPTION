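Package: trialscreen
Title: Bayesian Screening Analysis for Umbrella Phase II Trial Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis engine for biomarker-stratified ("umbrella") phase II
    oncology trial arms screened with conjugate Bayesian decision rules.
    Derives per-patient efficacy endpoints (confirmed objective response under
    RECIST v1.1, durable clinical benefit at the fourth protocol CT, PFS, TTP,
    OS, best percentage change in target-lesion sums) from longitudinal tumour
    assessments; estimates true response and benefit rates with beta-binomial
    posteriors and median survival times with an exponential-inverse-gamma
    model; drives GO/NO-GO screening decisions from posterior exceedance
    probabilities with simulated operating characteristics; and tests per-gene
    enrichment of pathogenic circulating tumour DNA (ctDNA) mutations in
    post-treatment versus baseline samples with a two-sided exact test. A
    seeded synthetic-cohort generator emulates the trial structure so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
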