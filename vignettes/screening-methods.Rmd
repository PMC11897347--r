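---
title: "Methods: Bayesian screening analysis for umbrella trial cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian screening analysis for umbrella trial cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialscreen)
```

## The setting

Umbrella phase II platform trials screen several targeted drugs at once,
each in a biomarker-defined cohort, and need an early, calibrated answer to
one question per cohort: is there enough signal of efficacy to justify
further development? `trialscreen` implements the analysis engine for one
such treatment arm: three cohorts (labelled B1, B2D, B2S by their defining
molecular aberrations), 6-weekly CT response assessment under RECIST v1.1,
28-day treatment cycles, and conjugate Bayesian screening of two co-primary
binary endpoints.

## Endpoint derivation

All timing is in integer days from the first dose (day 0); calendar dates
are out of scope because every endpoint rule is relative.

**Objective response (OR)** requires a CR or PR assessment confirmed by a
second CR/PR at least `confirm_window_days` later with no intervening PD.
The default window of 28 days is the RECIST v1.1 confirmation convention;
the trial definition says only "confirmed", so the window is exposed as a
parameter.

**Durable clinical benefit (DCB)** means remaining progression-free at the
fourth protocol CT (~24 weeks on the 6-weekly schedule), with 154 days
(22 weeks) as the minimum day on which that CT can qualify — a patient whose
fourth scan falls on day 161 qualifies, one who progresses at the second
scan does not. Patients whose follow-up ends before the threshold without
progression are *not evaluable*; by default they remain in the denominator
as non-successes (a conservative intention-to-treat reading within the
analysis population), switchable to exclusion via `na_rule = "exclude"`
because trial reports differ on this convention.

**PFS/TTP/OS** use standard conventions the trial description leaves
implicit: PFS events are progression or death, whichever first; TTP counts
progression only, with death before progression censoring TTP at the death
date; otherwise censoring is at last contact. These choices force
`ttp_days == pfs_days` with `ttp_event` implying `pfs_event`, both asserted
as suite-wide invariants.

**Best percentage change** in the target-lesion sum is
`100 * (min post-baseline sum − baseline) / baseline`, with +100% assigned
to patients who discontinued without a post-baseline measurement (the
waterfall-plot convention). A zero baseline with post-baseline measurements
is an error, not a silent infinity.

## Conjugate posterior models

**Rates.** With `s` successes among `n` evaluable patients and a Beta(1, 1)
prior, the posterior is Beta(1 + s, 1 + n − s). Two reporting choices are
deliberate and were forced by internal consistency of the reported-summary
format the package reproduces:

* the point estimate is the posterior **median**, not the mean — with 2/26
  successes the median is 9.8% while the mean 3/28 = 10.7% is not what the
  reporting format produces;
* intervals are **equal-tailed** (0.025 and 0.975 quantiles), not HPD.

Quantiles come from `stats::qbeta` (the regularised-incomplete-beta
inverse). The exceedance probability P(p > p\*) is `pbeta(p*, a, b,
lower.tail = FALSE)`; for integer parameters the identity
P(Beta(a, b) ≤ x) = P(Binomial(a + b − 1, x) ≥ a) gives an exact
enumeration cross-check, used in the tests alongside a 10⁷-draw Monte-Carlo
oracle.

**Survival.** Survival times are modelled as exponential with hazard λ. The
minimally informative IG(0.001, 0.001) prior is interpreted as shape 0.001,
scale 0.001 on the exponential *mean* — equivalently a Gamma(shape 0.001,
rate 0.001) prior on λ, the standard minimally-informative conjugate
pairing; the parameterisation is stated here because shape/scale vs
shape/rate conventions differ across software. With `d` events and total
follow-up `T` (censored patients contribute time only), λ | data ~
Gamma(0.001 + d, 0.001 + T). The reported quantity is the median survival
M = ln 2 / λ, a strictly decreasing transform, so quantiles map through
with order reversal: the 95% CrI for M is (ln 2 / q₀.₉₇₅, ln 2 / q₀.₀₂₅) of
the Gamma. Days convert to months at 365.25/12 (configurable). Because
patient-level survival times are not public, the survival model is validated
by parameter recovery on seeded exponential simulations (posterior median
within 10% of truth at n = 500), scale equivariance, and Monte-Carlo
quantile agreement, rather than against published medians.

## The screening decision

A cohort screens GO when P(true rate > relevant rate) ≥ `go_pp_cutoff`. The
relevant-rate default of 0.30 for both OR and DCB is the unique round value
consistent with the exceedance probabilities the reporting format pairs
with the 6/26 and 2/26 posteriors (0.26 and < 0.01); it is documented as
inferred and fully overridable. The cutoff default 0.90 is a conventional
screening placeholder — the trial's exact operating value lives in its
design publication and is out of scope — so `operating_characteristics()`
simulates the GO probability across true rates for any chosen cutoff
(seeded, with Monte-Carlo standard errors; the curve's monotonicity in the
true rate is a tested invariant). A single decision look is implemented;
interim-look cadence is not.

## ctDNA enrichment

Variants are pathogenic if frameshift, in-frame indel of exactly 3 nt,
splice annotated pathogenic, or CADD strictly above 20. "Trinucleotide
indel" is read as length exactly 3; `trinucleotide_rule = "divisible3"`
relaxes it to any in-frame length. Detectability is per patient: at least
one pathogenic variant of the gene at the timepoint, in a sample with ≥9 ng
cfDNA (insufficient samples drop out of both numerators and denominators).
Baseline and post-treatment sample sets are compared **unpaired** — the two
denominators differ (e.g. 36 vs 27 sufficient samples), so a paired test is
not even well-defined on these margins.

The per-gene test is the two-sided Fisher exact test under the
minimum-likelihood convention: sum the hypergeometric probabilities of all
tables (margins fixed) no more probable than the observed one, comparing
with relative tolerance 1 + 1e−7 to absorb floating-point ties. The
enumeration is a few lines over `stats::dhyper`; `stats::fisher.test` is the
independent cross-check in the tests, never the implementation, so both
routes stay visible. Two-sided exact p-values are convention-dependent:
mid-p or tail-doubling variants give different values (on the 3/36 vs 11/27
table the minimum-likelihood p is 0.00457, which other conventions or
roundings may print as 0.004), which is why the suite pins the convention
explicitly. No multiplicity correction is applied to the significance flag
(conventional p < 0.05 screening); a Benjamini–Hochberg q-value column is
emitted for information.

## The synthetic-cohort generator

The generator exists so that every pipeline stage — readers, derivation,
posteriors, decisions, enrichment — runs and is testable without patient
data. Its defaults are the study conditions it emulates:

| parameter | default | rationale |
|---|---|---|
| cohort sizes | B1 5, B2D 30, B2S 19 | registered-cohort structure |
| per-protocol exclusion | 0.11 | ~6/54 excluded |
| true OR rate | 0.08 (all cohorts) | low observed response |
| true DCB rate | B2D 0.24, others 0.15 | moderate benefit rates |
| OS median (months) | B1 7.0, B2D 6.1, B2S 9.8 | cohort-level survival |
| PFS median (months) | 2.5 | < 3 months in all cohorts |
| CT interval / cycle | 42 d / 28 d | protocol schedule |
| dropout median | 60 months | censoring is rare (2/48) |
| insufficient-DNA prob. | 0.25 | ~36/48 sufficient baselines |
| enriched genes | SMARCA4 ×7.6 odds, FOXP1 ×8.6 | detection frames ≈ 3/36→11/27 and 0/36→4/27 |

Latent progression and death times are exponential at the configured
medians, drawn *conditionally* on each patient's OR/DCB indicators (a DCB
patient's progression and death fall beyond the fourth CT; a responder's
beyond the confirming scan — memorylessness makes these shifted draws).
Progression is observed only at the next scheduled CT (interval-censored
onto the grid, as RECIST progression actually is); death is observed
exactly. One global seed drives everything; the ctDNA stream derives from
it (`seed + 1`) so patient and variant tables can be regenerated
independently but reproducibly.

What the generator does **not** emulate: tumour-growth kinetics (lesion
sums are noise around categorical states), VAF dynamics, correlated
gene co-occurrence, informative censoring, or scan-date jitter. Passing
tests therefore demonstrate the *analysis engine's* correctness and
calibration under the stated stochastic structure, not robustness to every
feature of real trial data.

Because derived DCB can be not-evaluable when a patient drops out early,
generator/deriver consistency is measured among evaluable patients: with
independent censoring the evaluable-only proportion estimates the
configured truth, whereas the conservative NA-as-failure rate (the default
for trial reporting) is biased low by exactly the dropout fraction.

## Numerical choices and problem sizes

* Beta and Gamma quantiles: `stats::qbeta` / `stats::qgamma`; no sampling
  in the reporting path.
* Exact-test tie tolerance: relative 1 + 1e−7.
* Formatting is centralised: rates as percent to 1 decimal, exceedance
  probabilities to 2, p-values to 3 (`<0.001` floor), survival in months to
  1 decimal — so printed strings are themselves testable.
* Degenerate inputs: `beta_binomial_update(0, 0)` returns the prior
  (summary "50.0 (2.5-97.5)"); an all-insufficient sample set makes the
  enrichment scan fail with an explicit error rather than divide by zero;
  an empty cohort list yields empty tables and a clean exit.
* Test problem sizes, chosen to give stable Monte-Carlo behaviour: 200
  replicate cohorts for generator/deriver consistency (pooled ~5,000 B2D
  patients, 3-binomial-SE band), 1,000 replicates for the null calibration
  of the enrichment scan, 10⁷ draws for the beta quantile oracle, 10⁶ for
  the survival oracle, n = 500 for survival parameter recovery.

## Known limitations

* The exponential survival model has constant hazard; it is the model the
  screening design specifies, not a recommendation for general survival
  inference.
* The GO cutoff default (0.90) is a placeholder for a design-specific
  operating value; decisions at other cutoffs should be explored through
  `operating_characteristics()`.
* Enrichment testing is per-gene and unpaired; it does not model
  within-patient acquisition of mutations or clonal structure.
* The data model deliberately supports a compact long-CSV dialect and a
  MAF-like subset (gene symbol, classification, CADD, timepoint), not the
  full MAF or VCF specifications.
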