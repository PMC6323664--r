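# stagecut

Outcome-based cut-point optimization and staging-system evaluation for
node-positive (N3) gastric cancer.

The 8th-edition UICC/AJCC TNM classification splits N3 gastric cancer at 15
metastatic lymph nodes (MLNs): N3a (7–15) versus N3b (> 15). Whether 15 is
the prognostically optimal boundary is an empirical question. `stagecut`
implements the full analysis a registry study would run to answer it:

1. **Eligibility screening** of a patient-level cohort CSV (gastric
   adenocarcinoma, gastrectomy, > 15 nodes examined, pN3, M0, ≥ 1 month of
   follow-up, …), with a deterministic first-failing-criterion exclusion
   report.
2. **Cut-point scan**: for every candidate boundary *c* in 7–20, the cohort
   is split at mln ≤ *c* vs > *c* and the two-group log-rank statistic

   χ²(c) = [Σᵢ (O₁ᵢ − E₁ᵢ)]² / Σᵢ Vᵢ,  E₁ᵢ = n₁ᵢ dᵢ / nᵢ,
   Vᵢ = n₁ᵢ n₂ᵢ dᵢ (nᵢ − dᵢ) / [nᵢ² (nᵢ − 1)]

   is computed over the pooled event times; the selected boundary is the
   (smallest) argmax of χ²(c).
3. **Three-band analysis** of the patients the old and new boundaries
   disagree on (e.g. 14–15 MLNs), with pairwise log-rank tests against the
   bands below and above.
4. **Two-step multivariate Cox validation**: step 1 adjusts the
   univariate-significant prognostic factors plus the eighth-edition N3
   split (modified split excluded); step 2 adds the modified split so the
   two N definitions compete in one model. Fitting is Newton–Raphson on the
   Cox partial likelihood (Breslow or Efron ties), written from the
   defining formulas and cross-checked against the `survival` package in
   the test suite.
5. **Stage re-grouping** of (pT, N3a/N3b) into stages IIB–IIIC under the
   8th-edition table (shipped as a YAML resource) and under the modified N3
   definition.
6. **Staging-system comparison** by homogeneity (likelihood-ratio χ² of the
   categorical-stage Cox model), discriminatory ability / gradient
   monotonicity (1-df linear-trend χ² with stages as an ordinal score), and
   AIC = −2 logPL + 2k (lower is better).

A synthetic-cohort generator with a *plantable* true cutoff (negative-
binomial MLN counts, registry-like covariate mix, proportional-hazards
survival with a step at the planted boundary, five-year administrative
censoring) makes every stage testable end to end without access to
restricted registry data.

## Worked example

```r
library(stagecut)

cfg    <- default_paperlike_config(n = 2753, seed = 1, true_cutoff = 13L)
bundle <- run_pipeline(cfg, out_dir = "results")
bundle
#> Cut-point analysis bundle
#>   eligible records: 2753
#>   selected cutoff: 13 (chi2 = 150.182)
#>              term     hr ci_low ci_high   p_value retained
#>     eighth_n3:N3b 0.9762 0.8467   1.126 7.313e-01    FALSE
#>  modified_n3:mN3b 1.7612 1.5306   2.027 7.672e-16     TRUE
#>      metric   modified     eighth   margin   winner
#>     lr_chi2   160.1025   118.6224  41.4801 modified
#>  trend_chi2   158.2800   116.5387  41.7414 modified
#>         aic 31246.9767 31288.4568 -41.4801 modified
```

Reading the output: the scan finds the strongest prognostic split of this
cohort at 13 MLNs (log-rank χ² = 150.2); in the step-2 Cox model the
modified N3b term (> 13 MLNs) keeps a hazard ratio of 1.76 (p < 0.001)
while the eighth-edition N3b term collapses to HR ≈ 0.98 (p = 0.73); and
the re-staged system built on the 13-MLN boundary beats the eighth-edition
grouping on all three performance metrics — which is exactly the behavior
planted into the simulated cohort.

`run_pipeline()` also writes TSV reports (screening tally, demographics
summary, scan table, three-band tests, per-stage counts and KM curves,
step-1/step-2 Cox tables, system evaluation) plus a MANIFEST and run log
into `out_dir`. A thin command-line front end lives in
`inst/scripts/stagecut.R`:

```sh
Rscript inst/scripts/stagecut.R simulate --out cohort.csv --seed 9
Rscript inst/scripts/stagecut.R scan --input cohort.csv --range 7:20 --min-group 20 --out scan.tsv
Rscript inst/scripts/stagecut.R run --input cohort.csv --out-dir results
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "stagecut", load_package = "installed")'
```

The suite checks the Kaplan–Meier and log-rank primitives against hand and
brute-force oracles, the Cox engine against `survival::coxph` (both tie
methods), the stage grouping cell by cell, and the Monte-Carlo operating
characteristics of the planted-cutoff analysis (cutoff recovery, two-step
verdict, system-comparison win rate, null calibration and the selection
inflation of the maximal statistic).

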