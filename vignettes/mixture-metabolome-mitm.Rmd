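---
title: "Pollutant mixtures, the adipose metabolome, and blood pressure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pollutant mixtures, the adipose metabolome, and blood pressure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmetab)
```

## The scientific problem

Lipophilic persistent organic pollutants (POPs) — organochlorine
pesticides, PCBs, PBDEs — accumulate in adipose tissue over years of
dietary exposure. Weight-loss interventions such as bariatric surgery
mobilize these stores into circulation, which may blunt the expected
post-surgical improvement in blood pressure. Because people carry
correlated mixtures of many POPs at once, single-chemical regressions
are both confounded and uninterpretable as policy targets; and because
the mechanism is unknown, an untargeted adipose metabolome offers a way
to look *between* exposure and outcome.

`popmetab` implements the full analysis chain for this design:

1. **Mixture effect.** Linear quantile g-computation of percent changes
   in blood pressure (SBP, DBP, MAP, pulse pressure at 6 months and 5
   years relative to baseline) on the joint POP mixture.
2. **Dual MWAS.** A metabolome-wide scan of the mixture on every
   feature's log2 intensity, and a second scan of every feature on the
   selected blood-pressure change.
3. **Multiplicity.** A raw p < 0.01 tier plus a PCA-based effective
   number of tests (Kaiser–Guttman) adjusted tier.
4. **Meet-in-the-middle.** Features significant in both scans,
   annotated against a reference library by m/z and retention time, and
   hypergeometric pathway overrepresentation on each side with overlap
   of the enriched pathways.

A synthetic-study generator with known ground truth makes each stage —
and the chain end to end — testable without access to subject-level
cohort data.

## The mixture model

Each chemical's concentrations are ranked into quantiles (quartiles by
default), giving integer indices $q_{ij} \in \{0, \dots, q-1\}$. The
outcome model is ordinary least squares:

$$
y_i = \beta_0 + \sum_{j=1}^{k} \beta_j q_{ij} + \gamma' z_i + \varepsilon_i,
$$

with covariates $z_i$: race/ethnicity (non-Hispanic white vs others),
sex, age in months, baseline BMI, and parents' income in four categories
against the "<\$25,000" reference; study site can be added for
sensitivity analyses. The overall mixture effect is
$\psi = \sum_j \beta_j$ — the expected outcome change when every
chemical moves up one quantile simultaneously — with
$\operatorname{Var}(\psi) = \mathbf{1}' \Sigma \mathbf{1}$ over the
chemical-coefficient covariance block, a normal-approximation 95% CI,
and a two-sided Wald p-value. The $\beta_j$ are the per-chemical
*partial effects*, partitioned into positive and negative sets; their
sum equals $\psi$ identically, and the package asserts this on every
fit. $\psi$ also equals the g-computation contrast — mean prediction
with all indices incremented by one minus mean prediction at the
observed indices — which the test suite verifies against an independent
`lm`/`predict` implementation to 1e-10.

Numerical choices worth knowing:

* **Cutpoints** are empirical quantiles with linear interpolation
  (type 7). A value exactly equal to a cutpoint falls to the *lower*
  category. Because the type-7 interpolation weight depends only on the
  sample size and probability, category assignment is invariant to any
  strictly increasing transform of a chemical — so quantizing raw or
  log2 concentrations gives identical designs, and $\psi$ is invariant
  to monotone re-expression of exposures.
* **Ties.** LOD-substituted non-detects share a single value; when ties
  empty a category the fit proceeds with a warning reporting realized
  category sizes rather than silently re-binning.
* **CIs are analytic** (delta-method on the linear model); bootstrap
  intervals are a non-goal.
* Percent-change outcomes enter in percentage points, so $\psi$ for a
  blood-pressure outcome reads directly as "% change per simultaneous
  one-quartile increase". Submixtures (e.g. OCPs only) re-quantize the
  subset and drop the other chemicals from the model entirely.

## Preprocessing conventions

* Non-detects are replaced by LOD/√2 (so an 0.1 ng/g LOD yields the
  conventional 0.0707 floor); descriptives (geometric means with
  normal-theory CIs on the log scale, Spearman correlations) are
  computed on the concentration scale before the log2 transform used in
  modelling.
* Features are filtered on detection rate ≥ 20% (fraction of
  non-missing *subject* cells; QC replicates are excluded from the
  denominator) and pooled-QC coefficient of variation ≤ 30%, computed
  as SD/mean of QC replicate intensities on the raw scale — the scale
  convention is a package decision, stated here because CV is not
  scale-free. The filter is idempotent and logs counts removed per
  rule.
* Remaining missing values are imputed with half of each feature's
  minimum observed intensity (per feature, raw scale, before log2).
  Half-minimum imputation slightly attenuates association estimates —
  visible in the synthetic recovery checks as a bias of a few percent —
  which is a property of the procedure, not a defect of the estimator.
* MAP = (SBP + 2·DBP)/3 and pulse pressure = SBP − DBP are exact closed
  forms; percent change is 100·(follow-up − baseline)/baseline. No
  random-forest QC signal correction is applied: the pipeline starts
  from post-correction intensities, and a pass-through hook is the
  place to plug one in.

## Effective number of tests

For each scan, PCA is applied to the predictor and response blocks
separately; Meff is the count of correlation-matrix eigenvalues
strictly greater than one (Kaiser–Guttman), and the adjusted threshold
is $\alpha / (M_\text{eff}^{(1)} + M_\text{eff}^{(2)})$. With an
exposure-block Meff of 2 and a metabolome Meff of 62 this gives
0.05/64 ≈ 0.00078; with a single selected outcome (Meff 1 by
definition), 0.05/63 ≈ 0.0008.

Two implementation decisions matter. First, a joint eigendecomposition
of $p \gg n$ features is rank-limited at $n - 1$, so a metabolome Meff
above that is impossible jointly; the package therefore computes Meff
*within each analytical mode* and sums across modes by default (a joint
option exists for sensitivity). Second, the Kaiser–Guttman rule is
strict: an exactly-unit eigenvalue — which only arises for constructed,
degenerate correlation matrices — counts zero and triggers a warning
rather than being silently nudged. Eigenvalues are computed from the
SVD of the standardized data matrix, which is exact and far cheaper
than forming a features-by-features correlation matrix.

## Annotation, overlap, and enrichment

A feature matches a library entry of the same analytical mode when
|m/z difference| ≤ 10 ppm **and** |RT difference| ≤ 10 s (both
configurable); all matches are returned ranked by ppm distance, with no
winner-takes-all collapse. Matching is monotone: widening either
tolerance never removes a match.

The meet-in-the-middle overlap intersects the significant sets of the
two scans at a named tier (raw 0.01 or adjusted). Pathway
overrepresentation is a one-sided hypergeometric test over explicit
feature→metabolite→pathway annotations — a declared simplification of
network-based tentative-annotation algorithms, which operate on adduct
rules this package does not model. Enrichment uses a looser raw
p < 0.05 input tier so enough features enter the test; a pathway is
*displayed* when p < 0.05 with at least three significant member
features, and pathways displayed on both sides are the overlapped
pathways. Every report names the tier it used.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the package targets, chosen once:

* **Exposures.** 57 subjects; six chemicals (p,p′-DDE, p,p′-DDT, HCB,
  PCB118, PCB153, PBDE47) with log-normal marginals on the cohort
  concentration scale (geometric SDs back-solved from geometric-mean
  CIs at n = 57) joined by a Gaussian copula with the Spearman→Pearson
  conversion $\rho = 2\sin(\pi \rho_s / 6)$. The rank-correlation
  target is a two-block structure (OCPs 0.5 within, PCBs/PBDE 0.6
  within, 0.15 across) — an assumption, consistent with pairwise POP
  rank correlations spanning roughly −0.2 to 0.9 in adipose panels,
  since the exact structure is not identifiable from published
  summaries. Values below LOD are flagged; with these marginals
  realized detection is effectively 100%, slightly cleaner than the
  96–98% seen for PCBs in tissue panels (log-normal tails are thinner
  than real ones).
* **Metabolome.** Four modes (C18±, HILIC±) at 500 features per mode by
  default (a `full_scale` flag switches to 3619/4824/7615/5292).
  Features are independent log-normal noise except for planted signal
  features, which add $\psi_f \times$ (mean chemical quartile index) to
  log2 intensity, so the scan estimand equals the planted value.
  Features matching the built-in annotation library inherit its m/z,
  RT and mode; library entries named `synthetic-met-###` are synthetic
  fillers (labelled as such) that give enrichment a realistic
  background. Pooled-QC replicates carry multiplicative noise at a
  configurable CV, and small designated fractions of junk features
  violate the detection and CV filters so the filters have work to do.
  Because features are mutually independent apart from the planted
  signal, per-mode Meff sits near min(p, n−1) — real metabolomes are
  far more correlated, which is exactly why the cohort-scale Meff (62
  for 21,350 features) is so much smaller. Passing tests on this
  generator therefore validate the estimators and plumbing, not the
  correlation structure of real LC-HRMS data.
* **Blood pressure and mediation.** Baseline SBP/DBP are normal at
  127(15)/76(11) mmHg. The 5-year SBP percent change carries a planted
  *total* mixture effect (default +6.4 points per simultaneous quartile
  increase) with part of it routed through designated mediator features
  (default: the tryptophan-pathway metabolites, exposure→feature
  −0.729 log2 units per quartile and feature→SBP −3.49% per doubling).
  The direct path is set to the total minus the mediated part, so the
  marginal quantile-g-computation estimand equals the planted total
  regardless of mediator count — this keeps recovery tests well-defined
  under the meet-in-the-middle premise that both marginal associations
  exist. Residual percent-change noise defaults to 12 points, matched
  to cohort-scale CI widths; other measures and the 6-month visit are
  noise around modest post-surgical declines.

Determinism: every generator derives its stream from the config seed
plus a fixed stage offset, so identical configs produce byte-identical
studies regardless of call order.

## Outcome selection and the pipeline

`run_pipeline()` fits all eight measure × visit mixture models, then
selects the outcome for the second MWAS programmatically as the one
whose CI excludes zero (smallest p among those; smallest p overall as a
fallback), overridable by configuration. Reports are stamped with a
hash of the configuration and the seed; any stage failure aborts with
the stage name, and partial report files are removed.

## Problem sizes used in the tests

The shipped suite runs the generator at 40–120 features per mode and
57–500 subjects, 100–500 replicates for calibration/coverage
(type-I error at raw 0.01 within 1% ± 1%; 95% CI coverage within
95% ± 2%), 2000 replicates for geometric-mean CI coverage, and one
end-to-end low-noise study at n = 500 that must recover the planted
6.4-point SBP effect within ±1.0. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that runs in
seconds; the estimators themselves have no size-dependent switches.

## Known limitations

* The mixture model is linear in quantile indices: no nonlinear or
  interaction terms, no bootstrap CIs, no binomial/survival links.
* FDR/q-value procedures are deliberately absent; the two-tier
  raw + Meff convention is the supported multiplicity scheme.
* Pathway enrichment is annotation-based ORA, not network inference;
  externally computed pathway p-values can be substituted where the
  overlap logic is still wanted.
* The generator does not simulate chromatograms, instrument drift,
  batch effects, or feature-feature correlation beyond planted signal.
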