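---
title: "Methods: MLN cut-point optimization and staging-system evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MLN cut-point optimization and staging-system evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagecut)
```

## The problem

The TNM N3 category for gastric cancer (at least 7 metastatic lymph nodes,
MLNs) is subdivided into N3a and N3b at 15 MLNs in the 8th edition of the
UICC/AJCC classification. That boundary matters: the final pathological
stage (IIB–IIIC) of an M0/N3 patient depends on whether they are N3a or
N3b at a given pT. `stagecut` implements the full statistical machinery for
asking whether a different MLN boundary stratifies prognosis better, and
for validating a candidate boundary against the incumbent.

The package is organized around a patient-level cohort table (one row per
gastrectomy patient: demographics, histology grade, tumor size, pT, nodes
examined, MLN count, surgery type, follow-up months, vital status). All
downstream stages operate on the screened N3 subset of such a table.

## Eligibility screening

`screen_cohort()` retains records that satisfy, in order: gastric primary
site; age ≥ 18; adenocarcinoma; partial or total gastrectomy; more than 15
lymph nodes examined; at least 7 MLNs (pN3); pT1–T4b; M0; follow-up of at
least one month; no multiple primaries; no remnant gastric cancer; and no
missing fields. Each excluded record is charged to the *first* failing
criterion in that order. The charging order is a design choice — the
clinical criteria themselves do not imply one — and first-failure charging
makes the exclusion report deterministic and exactly reconcilable
(`n_input = n_eligible + sum(exclusions)`). A predicate only fires on a
definite violation, so records with missing fields fall through to the
final "incomplete record" criterion rather than being charged to a
comparison against `NA`; a missing tumor size therefore counts as an
incomplete record, not a size violation. "Survival < 1 month" is compared
numerically (`followup_months < 1`), so fractional-month inputs behave
sensibly.

## Survival primitives

The Kaplan–Meier estimator and the log-rank family are implemented from
their defining formulas rather than wrapped from another package, because
the cut-point scan *is* the contribution here and its statistic must be
fully transparent. Conventions:

* The risk set at time *t* is everyone with follow-up ≥ *t*; a subject
  censored exactly at an event time is at risk for that event (the
  standard convention).
* Five-year overall survival is the KM step function evaluated at exactly
  60 months; beyond the last follow-up the last estimate is carried
  forward.
* The two-group log-rank variance term uses the hypergeometric form with
  the guard V = 0 when only one subject is at risk (the formula's
  denominator vanishes there). The k-group version combines the
  observed-minus-expected vector of the first k − 1 groups with its
  estimated covariance; a singular covariance (e.g. a group whose events
  never overlap the others) falls back to a pseudoinverse.
* No continuity correction is applied anywhere; p-values are upper-tail
  χ² probabilities, which reproduces the astronomically small magnitudes
  (~1e-36) that strong splits of large cohorts produce.
* Zero events in total is a documented degenerate result (χ² = 0, p = 1),
  not an error; an empty group is an error.

The test suite holds these primitives to a brute-force O/E/V oracle on
small fixtures and to `survival::survfit`/`survdiff` on random cohorts
(agreement to 1e-6 or better).

## The cut-point scan

`scan_cutpoints()` evaluates each candidate boundary in 7–20 (the plausible
window around the incumbent 15) by the two-group log-rank χ² of mln ≤ c
versus mln > c, and selects the smallest argmax. Two defaults deserve
comment:

* **`min_group = 20`**: the χ² statistic degenerates when one side of the
  split holds only a handful of patients, so cutoffs leaving fewer than 20
  subjects on either side are inadmissible. Large N3 cohorts are unaffected
  (every cutoff in 7–20 leaves hundreds per side).
* **No multiplicity correction**: the selected boundary's p-value is the
  raw log-rank p, which is anti-conservative because it is the maximum of
  ~14 correlated statistics. The package documents this rather than
  corrects it: the acceptance suite measures the null rejection rate of
  the *fixed* split (calibrated to ~5%) against that of the *maximal*
  scan (well above 10%). Users who need honest selection p-values should
  treat the scan as exploratory and validate on independent data — which
  is exactly what the two-step Cox stage is for.

`three_band_analysis()` isolates the patients the incumbent and candidate
boundaries disagree on (14–15 MLNs when the scan selects 13) and tests them
pairwise against the band below and the band above. If the reassignment is
correct, the middle band should be indistinguishable from the high band and
clearly worse than the low band.

## Two-step multivariate Cox validation

`fit_cox()` maximizes the Cox partial likelihood by Newton–Raphson with
step-halving, supporting Breslow (default) and Efron tie handling. Breslow
is the default because it is the default of the major commercial packages
used for this kind of registry analysis, which makes results comparable;
Efron is a flag away and the engine is validated against
`survival::coxph` under both. Convergence is declared when the log partial
likelihood changes by less than 1e-9; coefficients diverging past |β| > 15
raise a complete-separation error rather than returning a runaway
estimate, and a singular information matrix (e.g. two identical terms)
raises rather than guessing.

Categorical factors are coded against fixed clinical reference levels
(age < 65, male, White, G1/G2, ≤ 60 mm, T1, partial gastrectomy, N3a,
mN3a). Univariate screening uses the k-group log-rank χ² per factor — a
single statistic per factor, including multi-level ones — with
significance at p < 0.05.

The two-step design answers "does the new boundary carry prognostic
information the old one does not?":

* **Step 1** fits the univariate-significant factors plus the
  eighth-edition N3 term, with the modified term deliberately excluded.
* **Step 2** adds the modified N3 term, so both N definitions sit in the
  same model. They disagree only on the reassigned patients (14–15 MLNs
  for boundary 13), so they are collinear-but-distinct by construction; no
  collinearity guard is applied beyond the separation error, and forcing
  the candidate boundary onto the incumbent (making the two terms
  identical) correctly fails with a singular-information error.

The verdict reports each N term's step-2 hazard ratio and p-value. In the
planted-cutoff simulations the modified term is retained and the eighth
term collapses in the large majority of replicates — and the verdict
symmetrically reverses when the hazard step is planted at 15 instead.

## Stage re-grouping and system evaluation

The (pT, N3a/N3b) → stage table for M0/N3 disease is shipped as a
declarative YAML resource (`inst/extdata/tnm8_n3_grouping.yaml`), verified
cell by cell against the published 8th-edition grouping: T1/N3a → IIB,
T2/N3a → IIIA, {T1,T2}/N3b and {T3,T4a}/N3a → IIIB, everything else →
IIIC. The modified system applies the same cells with its own N boundary,
so moving a patient from N3a to N3b can only upstage — an invariant the
tests assert. Empty stage classes are reported with count 0, never
dropped.

`evaluate_system()` scores a staged cohort with three conventional
metrics:

* **Homogeneity**: likelihood-ratio χ² = 2(logPL of the categorical-stage
  Cox model − logPL of the null model), df = non-empty stages − 1. Larger
  means survival within stages is more homogeneous relative to between
  stages.
* **Discrimination / gradient monotonicity**: the 1-df trend χ² from a Cox
  model with stage entered as a consecutive-integer score in the declared
  order. The likelihood-ratio form is the default; a score-test variant
  (`trend_method = "score"`) is offered since the classical methodology
  can be read either way — the two differ negligibly in practice, and the
  choice is surfaced rather than buried. Because the scored model is
  nested in the categorical one, trend χ² ≤ LR χ² always; the tests
  assert this in every replicate.
* **AIC** = −2 logPL + 2k with k = the categorical model's coefficient
  count (no small-sample correction). With equal parameter counts the AIC
  margin between two systems is exactly minus the LR-χ² margin — an
  algebraic identity the tests check — so AIC adds information only when
  re-grouping empties a stage class.

`compare_systems()` refuses to compare evaluations with different subject
or event counts, since the metrics are only meaningful on the same cohort.

## The synthetic-cohort generator

`generate_cohort()` emulates the structure of a combined Eastern/Western
registry N3 cohort. The defaults in `default_paperlike_config()` are the
study conditions, chosen once from the published margins of such cohorts
and not tuned afterwards:

* **MLN counts**: negative binomial (mean 12, dispersion 2) truncated to
  [7, 90] by inverse-CDF sampling, giving median 14, P(mln ≤ 13) ≈ 0.49,
  P(mln ≤ 20) ≈ 0.77 — matching the registry margins (median 14, range
  7–90, ~48% at or below 13).
* **Nodes examined**: MLN count plus a Poisson(12) offset, floored at 16
  (the eligibility floor), reproducing a median around 26.
* **Covariates**: 61.7% male; ethnicity mix (White 24%, Asian 54%, Black
  9%, Hispanic 13%, Native American 0.7%); 84% G3/G4; age ~ N(62.4,
  13.4²) truncated at 18; log-normal tumor size with median 60 mm; pT mix
  weighted to T4a (2.1/4.2/26.6/50.2/16.9%); 41% total gastrectomy.
* **Survival**: proportional hazards with an exponential baseline (0.013
  per month) — the simplest model satisfying proportional hazards exactly,
  which keeps Cox parameter-recovery tests clean; a Weibull shape
  parameter defaults to 1 and is available for sensitivity work. The log
  hazard adds covariate effects (age ≥ 65: ln 1.47, Asian: ln 0.66, pT:
  ln 1.2 per category step — magnitudes typical of multivariate registry
  estimates) and the planted step `log_hr_step` (default ln 1.6) when the
  MLN count exceeds `true_cutoff` (default 13). The baseline rate was set
  once so that five-year survival lands near 30%/15% below/above the
  planted boundary. An optional linear-in-MLN term exists for probing scan
  robustness.
* **Censoring**: administrative at 60 months (survivors carry full
  five-year follow-up) plus an optional independent exponential
  loss-to-follow-up process, off by default. Follow-up is floored at one
  month because the generator emulates the *post-screening* population,
  whose design excludes sub-1-month survival.
* **Determinism**: one global seed and a fixed draw order (covariates,
  node counts, event times, censoring times, ineligibility flags); equal
  configs give identical cohorts, and configs round-trip through YAML at
  full float precision.
* **Planted ineligibility**: an optional fraction of records is mutated to
  violate exactly one randomly chosen screening criterion, with the
  planted reasons recorded in an attribute so screening tests can assert
  exact recovery.

What the generator does *not* emulate: registry-specific coding quirks,
calendar-period effects, non-proportional hazards, correlation between
covariates (they are drawn independently), or informative censoring.
Passing Monte-Carlo tests on these cohorts therefore demonstrates that the
machinery is correct and well calibrated under the stated model — not that
any particular clinical boundary is optimal in real populations.

## Monte-Carlo problem sizes

The simulation-based checks use: 200 replicates at n = 2000 for cutoff
recovery (selected boundary within ±1 of the planted 13 in ≥ 90%); 100
replicates at n = 2753 for the two-step verdict and the three-metric
system comparison (≥ 80% win rates); 500 null replicates at n = 500 for
log-rank calibration (fixed-split rejection within [0.03, 0.07] at
α = 0.05) and selection inflation (maximal-scan rejection > 0.10); and 50
random cohorts for Cox agreement with the independent implementation
(coefficients to 1e-4, both tie methods). These sizes give the binomial
assertions comfortable margins while keeping the full suite in the
few-minute range.

## Known limitations

* The scan optimizes a single boundary; multi-cutpoint (3+ group)
  optimization and permutation-adjusted selection p-values are out of
  scope.
* No proportional-hazards diagnostics (Schoenfeld residuals) or
  time-varying coefficients; the Cox validation inherits the PH
  assumption.
* KM confidence bands and weighted log-rank variants (Wilcoxon/Peto) are
  not provided.
* The staging table covers the four stage classes M0/N3 disease can
  occupy; other TNM cells are out of scope, as are clinical (cTNM) and
  post-neoadjuvant (ypTNM) staging.
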