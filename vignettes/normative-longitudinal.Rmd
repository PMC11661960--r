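---
title: "Normative modeling of longitudinal cortical thickness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modeling of longitudinal cortical thickness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the synthetic study design, and the
numerical and inferential choices behind `ctnorm`, in the spirit of the
methods sections of other model-based Bioconductor packages. Nothing here
states an empirical result; the numbers the package produces come from
its test suite and from `scripts/acceptance.R`.

## 1. The hierarchical normative model

For each cortical region (ROI) the thickness of a healthy reference scan
is modelled as linear in age within a *batch* — a (scanner, sex) cell —
with batch parameters partially pooled through shared hyperpriors:

$$
\begin{aligned}
y &\sim N\!\big(a_j + b_j (\mathrm{age} - \mathrm{age}_0),\; \sigma_j^2\big) \\
a_j &\sim N(\mu_a + \delta_f \cdot \mathrm{female}_j,\; \tau_a^2), \qquad
b_j \sim N(\mu_b, \tau_b^2), \qquad
\log \sigma_j \sim N(\mu_{\log\sigma}, \tau_{\log\sigma}^2).
\end{aligned}
$$

Assumptions worth making explicit:

- **Linearity in age per batch.** Because every scanner contributes its
  own intercept and slope, the population-level age trajectory implied by
  a multi-scanner reference is piecewise linear rather than a single
  global line; no spline basis is used.
- **Crossed batch structure.** Batches are fully crossed scanner × sex
  cells, each with its own noise SD; sex additionally contributes a
  global intercept offset $\delta_f$ in the hyperprior mean. This keeps
  cells estimable while respecting sex and scanner as batch effects.
- **Gaussian likelihood, homoscedastic in age.** Non-Gaussian (e.g.
  skewed) likelihoods and age-dependent noise are out of scope.

Age is centred at the reference-training mean age ($\mathrm{age}_0$),
stored in the model and reused verbatim at transfer and scoring time, so
"intercept" always means "expected thickness at the reference mean age".

### Estimation

The default backend is a deterministic empirical-Bayes EM:

- **E-step.** Given the hyperparameters and $\sigma_j$, the posterior of
  $(a_j, b_j)$ is conjugate Gaussian; $\log\sigma_j$ is updated as its
  1-D posterior mode (MAP) using the expected residual sum of squares.
- **M-step.** Hyperparameter updates use the batch posterior moments,
  *including* the posterior variances: $\tau_a^2$ and $\tau_b^2$ add the
  posterior covariance diagonal, and $\tau_{\log\sigma}^2$ adds a Laplace
  approximation of the posterior variance of $\log\sigma_j$
  ($1/(2n_j + \tau_{\log\sigma}^{-2})$). Without these terms the
  between-batch scales collapse toward zero — an EM shrinkage spiral that
  would freeze transfer to new scanners (observable as badly
  mis-calibrated deviation SDs).

Iteration stops when the largest absolute hyperparameter change falls
below $10^{-6}$, with a cap of 2000 iterations; a capped fit is flagged
in `fitMeta()$converged`, and the pipeline excludes flagged ROIs from the
downstream FDR families. Batches with fewer than `minBatchN` (default 10)
scans are fully shrunk to the hyperprior mean. The EM is seedless and
reproducible. An optional MCMC backend (JAGS via `rjags`) fits the same
model with full posteriors; the test suite checks that the two backends
agree on fitted normative surfaces and noise levels within 5% on
identifiable data.

### Transfer to unseen scanners

`transferModel()` freezes the reference hyperparameters and estimates the
new (scanner, sex) cells' $(a, b, \sigma)$ as posterior modes given
held-out local controls. The shrinkage behaviour is the defining
contract: with no adaptation data a new cell sits exactly at the
hyperprior mean; with increasing data it converges to the local OLS
estimates; in between, under a symmetric age design, the intercept lies
strictly between the two. The scanners' parameters matter far more than
the hyperpriors once a few hundred local controls are available, so
calibration on a new scanner is limited mainly by the adaptation sample
size (estimation error of a cell mean scales as
$\sigma/\sqrt{n_\text{cell}}$, inflated when the local age distribution
is off-centre relative to $\mathrm{age}_0$).

### Deviation scores and predictive uncertainty

`scoreDeviations()` emits $z = (y - \hat\mu)/\hat s$ per scan × ROI, each
scan scored with its own scanner's cell. By default
$\hat s^2 = \sigma_j^2 + x^\top C_j x$ with $C_j$ the posterior
covariance of $(a_j, b_j)$ and $x = (1, \mathrm{age}-\mathrm{age}_0)$:
including parameter uncertainty keeps extremes calibrated at the edges of
the age range, at the cost of making the predictive variance a convex
quadratic in age whose vertex sits slightly off the age centre whenever
the intercept–slope posterior covariance is non-zero. A noise-only SD
(`varMode = "noise"`) is available for sensitivity checks; which variant
published studies use is typically unstated, so the default is the more
conservative one and is recorded in the model object.

## 2. The synthetic study

The generator produces data with the statistical structure the analysis
assumes, at configurable scale. Defaults are fixed once to emulate the
kind of 10-year first-episode-psychosis study the package targets:

- **Reference cohort**: 10 sites × 100 controls (the real reference pools
  are two orders of magnitude larger; size only affects hyperparameter
  precision), ages uniform 18–65, intercepts around 2.5 mm (SD 0.08 mm
  between sites, 0.25 mm between ROIs), slopes around −0.005 mm/year,
  noise SD around 0.12 mm (log-normal between sites), female offset SD
  0.02 mm.
- **Clinical cohort**: 218 controls and 79 patients at waves ~0, ~1 and
  ~10 years on 3 scanners keyed to waves (wave 0 on scanners A/B, wave 1
  on B, wave 2 on C — scanners succeeding each other without temporal
  overlap); patients on average 6 years younger than controls (with a
  proportionally tighter SD), mirroring the significant baseline age
  difference such cohorts show; per-wave attrition 15% then 65%,
  matching 79 → 67 → 23-style retention.
- **Diagnosis effect**: a shift of `dxEffectBaseline` (default −0.5)
  z-units on an affected ROI subset, attenuating as
  $\Delta(t) = \Delta_0 e^{-t/\tau}$ with $\tau = 4$ years — so the
  effect is −0.5 z at inclusion, ~78% of that at 1 year and ~8% at 10
  years.
- **Symptoms**: PANSS domains per patient as subject-level baselines
  (total 64 ± 14 points) plus a linear time slope (total −1.4
  points/year), optional coupling of selected ROI deviations (points per
  z-unit), occasion noise (SD 4 points), clipped at the instrument floors
  (clipping is counted in the object metadata). Domains are generated
  independently rather than summing subscales, since each is modelled
  separately downstream.
- **Dependence**: ROIs are conditionally independent given one shared
  per-subject offset (default 0.2 × noise SD), which induces the
  within-subject correlation the longitudinal models' random intercept
  absorbs without simulating a full 150×150 covariance. The true
  within-subject correlation structure of regional deviations is unknown;
  this is a modelling choice, configurable via `subjectOffsetSd`.
- **Attrition**: monotone dropout per follow-up wave, MCAR by default;
  MNAR couples dropout odds to the baseline median deviation with a
  configurable logistic coefficient.
- **Quality control**: a scalar integer metric per scan, exceeding the
  conventional cut of 5 with probability `qcOutlierRate`; nothing else of
  surface reconstruction is emulated.

Two seeding decisions matter for experiments. The scanners' true
parameters depend only on `config@seed`, while `generateClinical()`
accepts a separate `subjectSeed`: replicate cohorts from *the same*
scanners (the correct design for size/power studies against one fitted
model) reseed subjects only. `generateAdaptation()` similarly draws
held-out local controls from the same scanner truth. Conflating the two
— redrawing scanners while holding the model fixed — produces grossly
mis-calibrated scores, and a test guards the distinction.

What passing tests on these data do **not** show: robustness to
non-Gaussian thickness distributions, age-varying noise, scanner drift
within wave, site-correlated demographics, or realistic spatial
correlation between neighbouring regions. The generator is a correctness
harness, not a brain simulator.

## 3. Downstream statistics

- **Extreme deviations** use strict inequalities (|z| > 2, not ≥),
  separately per tail; the threshold is recorded with every summary and
  configurable. Missing z are excluded from numerator and denominator.
- **Per-ROI case–control contingency tests** are Pearson chi-squares
  without continuity correction (Yates behind a switch), summarised by
  Cramér's V $= \sqrt{\chi^2/n}$; zero-margin tables are flagged with
  p = 1, V = 0. BH-adjusted and raw p-values are both reported, since
  published analyses are ambiguous about which was used at this step.
- **Per-subject extreme counts** are compared with a Mann–Whitney test
  using midranks and a tie-corrected normal approximation, or exact
  enumeration over all group assignments when both groups have ≤ 8
  subjects. The Wilcoxon/Mann–Whitney naming in the literature refers to
  the same two-sample rank test; it is implemented once. The CL effect
  size is $U/(n_1 n_2)$, oriented as
  $P(\text{SCZ count} > \text{CTRL count}) + \tfrac12 P(\text{tie})$ —
  above 50% means patients have more extreme deviations (the published
  orientation is usually unstated; this one is fixed and documented).
- **Mixed models** all share one form: response ~ fixed effects + subject
  random intercept, REML by default, fitted with `lme4`. Inference is
  Wald t on residual degrees of freedom (n_obs − n_fixed) — simple and
  deterministic, possibly differing from unstated published df methods.
  Boundary fits (subject variance → 0) fall back to OLS with a flag,
  which is the same estimator at the boundary. The signed effect size per
  coefficient is $d = \mathrm{sign}(\beta)\, 2|t|/\sqrt{df}$. FDR
  families are: one coefficient × one response family across ROIs, never
  pooled across coefficients.
- **Wave contrasts for PANSS** come from a companion model with wave as a
  categorical factor, accompanied by *unpaired* pooled-SD Cohen's d
  between per-wave samples — attrition breaks pairing, and the paired
  alternative would silently drop dropouts.
- **Attrition tests** default to pooled-variance t (so that the two-group
  summary-statistic ANOVA identity F = t² holds exactly); Welch and a
  rank-based sensitivity output are available, plus a logistic
  completer ~ baseline-variables model offered as a sensitivity analysis
  without claiming equivalence to any published specification.
- **Printed-table utilities** reconstruct one-way ANOVA F from group
  means/SDs/sizes and recompute composition percentages with half-up
  integer rounding, the convention of printed demographic tables.

### The recovery estimand under attenuation

The generator's diagnosis effect decays exponentially while the analysis
model is linear in time (diagnosis + diagnosis×time). The linear model's
estimand is therefore the weighted least-squares projection of
$\Delta(t)$ onto $(1, t)$ over the realised visit-time distribution — at
the default design ($\tau = 4$ y, waves 0/1/10, 15% attrition/wave) the
projected conditional baseline effect is ≈ −0.47 for a true −0.5, about
6% toward zero. Recovery checks in the acceptance suite therefore
compare the fitted coefficients against both the analytic projection and
the nominal −0.5, requiring median bias below 10% in each case.

### Size of the interaction test

With ~120 subjects, three waves, heavy final-wave attrition and jittered
visit times, the Wald interaction test runs near the top of its nominal
band (the acceptance suite requires 2–8% at α = 0.05): the few
long-delay observations carry high leverage and the residual-df t is
only an approximation there. This is the documented cost of the simple
deterministic inference; Satterthwaite-style corrections are out of
scope.

## 4. Problem sizes and tolerances

The test suite runs on deliberately small cohorts (6–10 reference sites
of 60–100 subjects, 6–20 ROIs) chosen so each check has adequate power
without excess computation; study-scale checks (218/79 subjects, waves
0/1/10) run in the acceptance suite with 12–40 ROIs. Calibration
experiments use 1500 adaptation controls per scanner and ~1000 held-out
validation controls — sizes at which transfer estimation error (~0.03 z)
is small against the ±0.1 mean / 0.9–1.1 SD calibration bands.
Key numerical tolerances: EM stop at $10^{-6}$ absolute hyperparameter
change; transfer inner loop at $10^{-10}$ in $\log\sigma$; hyper-scale
floors ($\tau$ parameters are floored at tiny positive values rather than
allowed to reach 0 exactly).

## 5. Known limitations

- No heteroscedastic-in-age noise or non-Gaussian likelihoods; published
  reference models built on such extensions cannot be reproduced
  weight-for-weight (and reusing their fitted weights is explicitly out
  of scope).
- Linear-in-time fixed effects: attenuation is captured through the
  interaction's sign and the projection estimand above, not as an
  explicit exponential fit.
- Wald/residual-df inference is anti-conservative for very sparse final
  waves (see §3).
- The serialization format stores batch posteriors as (mean, covariance)
  pairs only; full posterior draws from the MCMC backend are not
  persisted.
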