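# popmetab

Linking lipophilic persistent organic pollutant (POP) mixtures measured
in adipose tissue to blood-pressure changes through the adipose
metabolome.

People carry correlated mixtures of lipophilic POPs (organochlorine
pesticides, PCBs, PBDEs) in adipose tissue. After a weight-loss
intervention these stores mobilize into circulation and may blunt the
expected improvement in blood pressure. `popmetab` is for
environmental-epidemiology and metabolomics analysts who want to
estimate the joint effect of such a mixture on an outcome and screen an
untargeted metabolome for mechanistic intermediates, with every step
reproducible and testable on synthetic data with known ground truth.

## What it computes

**Quantile g-computation.** Each chemical is ranked into quartiles
(indices 0–3) and the outcome is regressed on all indices jointly plus
covariates:

    y_i = b0 + sum_j b_j q_ij + g' z_i + e_i

The overall mixture effect is `psi = sum_j b_j` — the expected outcome
change for a simultaneous one-quartile increase in every chemical —
with `Var(psi) = 1' Sigma 1` over the chemical-coefficient covariance
block, a normal 95% CI, and per-chemical partial effects `b_j` that sum
to `psi` identically.

**Dual MWAS with Meff correction.** One scan fits the mixture against
every feature's log2 intensity (estimates `psi` per feature); the other
fits each feature against the selected blood-pressure percent change
(`beta` = % change per doubling of intensity). Significance uses a raw
p < 0.01 tier plus a PCA-adjusted tier
`alpha / (Meff_predictors + Meff_response)`, where Meff counts
correlation-matrix eigenvalues > 1 (Kaiser–Guttman), computed per
analytical mode and summed for the metabolome.

**Meet-in-the-middle.** Features significant in both scans are
annotated against a reference library (±10 ppm m/z, ±10 s RT, same
mode), and each side feeds a hypergeometric pathway
overrepresentation; pathways displayed on both sides (p < 0.05 and ≥ 3
significant members) are the overlapped pathways.

**Synthetic studies.** `sim_config()`/`simulate_study()` generate
complete studies — Gaussian-copula correlated log-normal exposures with
LOD censoring, four-mode LC-HRMS feature tables with planted effects
and QC replicates, covariates, and longitudinal blood pressure with a
planted, partially mediated mixture effect — with full ground truth for
recovery tests.

## Worked example

```r
library(popmetab)

cfg <- sim_config(modes = c("C18-" = 120L, "C18+" = 120L,
                            "HILIC-" = 120L, "HILIC+" = 120L),
                  n_signal_features = 10L, seed = 1L)
report <- run_pipeline(run_config(sim = cfg))
report
#> Pipeline report (config af462570, seed 1)
#> Selected outcome: sbp_pct_year5
#> Mixture effects:
#>            outcome   psi ci_low ci_high p_value
#> 1   sbp_pct_month6  0.25  -4.09    4.60   0.910
#> 2   dbp_pct_month6  2.55  -2.26    7.36   0.300
#> 3   map_pct_month6  1.39  -1.81    4.60   0.390
#> 4 pulse_pct_month6 -3.62 -19.51   12.27   0.660
#> 5    sbp_pct_year5  7.29   1.68   12.90   0.011
#> 6    dbp_pct_year5  0.72  -4.65    6.09   0.790
#> 7    map_pct_year5  4.10  -0.28    8.48   0.066
#> 8  pulse_pct_year5 11.96  -3.39   27.32   0.130
#> Meff: exposures = 2 | metabolome = 154 | adjusted alpha = 0.00032 / 0.00032
#> Overlap features: 1 | overlapped pathways: 0
```

This 57-subject study carries a planted total effect of +6.4% on
five-year SBP per simultaneous quartile increase: the fit recovers
7.29% (CI 1.68–12.90) — significant, while the other seven
measure/visit combinations are null as planted — and the pipeline
selects five-year SBP for the second scan. At this sample size the
meet-in-the-middle keeps only one mediator feature, mirroring how
underpowered single-feature overlap is in a real cohort of this size:

```r
report$overlap[, c("feature_id", "metabolite", "psi", "beta")]
#>      feature_id        metabolite        psi      beta
#> 1 C18pos_F00002 synthetic-met-002 -0.6427226 -6.695621
```

The per-chemical decomposition of the headline fit:

```r
report$mixture_fits[["sbp_pct_year5"]]
#> Quantile g-computation fit (sbp_pct_year5, n = 57, q = 4)
#>   psi = 7.290  [1.681, 12.900]  p = 0.0109
#>   partial effects:
#> pp_DDE pp_DDT    HCB PCB118 PCB153 PBDE47
#>  3.242  0.680  0.185  3.120 -1.726  1.790
```

At n = 500 with low noise the same pipeline recovers the planted
effects tightly and the planted tryptophan-pathway mediators appear in
both scans and in the overlapped pathways (see the tests and the
acceptance script).

## Package layout

- `R/sim-config.R`, `R/sim-generate.R` — synthetic-study configuration
  and generators (copula exposures, metabolome, covariates, blood
  pressure), built-in annotation and pathway libraries.
- `R/preprocess.R` — LOD substitution, log2 transforms, feature
  filters, half-minimum imputation, percent-change outcomes,
  descriptives.
- `R/mixtures.R` — quantization and quantile g-computation
  (`fit_qgcomp`, `fit_submixture`).
- `R/mwas.R` — both scans, Meff, adjusted alpha, significance
  summaries.
- `R/mitm.R` — annotation, overlap, pathway ORA, bubble-plot export.
- `R/orchestration.R`, `R/io.R` — `run_pipeline()`, report/study
  readers and writers.
- `vignettes/mixture-metabolome-mitm.Rmd` — the methods vignette:
  model details, conventions, generator assumptions, limitations.
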