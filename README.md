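# ctnorm

Normative modeling of longitudinal regional cortical thickness with
transfer to unseen scanners, and the downstream case–control statistics
used in long-term follow-up studies of first-episode psychosis.

## The problem

Longitudinal clinical MRI studies almost inevitably change scanners over a
decade of follow-up, and raw cortical-thickness (CT) estimates are
confounded by scanner, sex and normal ageing. Normative modeling addresses
this by fitting, on a large healthy reference cohort, a per-region model
of thickness as a function of age with scanner and sex as batch effects,
and then expressing every clinical scan as a deviation z-score relative to
the prediction for that person's age, sex and scanner. Deviations are
comparable across scanners and timepoints, so diagnosis effects, their
evolution over time, and their coupling to symptoms can be analysed on a
common scale.

`ctnorm` implements that pipeline end to end for ROI-wise thickness
tables, for researchers analysing multi-site longitudinal cohorts:

- **Hierarchical Bayesian normative models** (`fitReference`), per ROI:

  a_j ~ N(mu_a + delta_f·female_j, tau_a²), b_j ~ N(mu_b, tau_b²),
  log sigma_j ~ N(mu_logsigma, tau_logsigma²),
  y ~ N(a_j + b_j (age − age₀), sigma_j²)

  for batches j = (scanner, sex), fitted by a deterministic
  empirical-Bayes EM (optional MCMC backend via JAGS).
- **Transfer to unseen scanners** (`transferModel`): batch parameters for
  new scanners are estimated under the frozen reference hyperpriors from
  held-out local controls, shrinking between the hyperprior mean (no data)
  and the local OLS estimates (much data).
- **Deviation scoring** (`scoreDeviations`): z = (y − mean)/SD with a
  posterior-predictive SD, plus calibration reports on held-out controls.
- **Extreme-deviation statistics** (`countExtremes`, `roiExtremeTest`,
  `subjectCountTest`): strict |z| > 2 thresholding by tail; per-ROI 2×2
  chi-square with Cramér's V; Mann–Whitney tests on per-subject extreme
  counts with the common-language (CL) effect size.
- **Longitudinal mixed models** (`roiDeviationLME`, `panssTimeLME`,
  `panssDeviationLME`): deviation ~ time + age₀ + sex + diagnosis +
  time×diagnosis with a subject random intercept, per ROI with
  Benjamini–Hochberg FDR across ROIs; PANSS trajectories and
  symptom–deviation associations in patients.
- **QC and attrition diagnostics** (`qcFilter`, `attritionTests`,
  `anovaFromSummary`, `demographicsTable`).
- **A synthetic cohort generator** (`SyntheticConfig`,
  `generateReference`, `generateClinical`, `generateAdaptation`) that
  reproduces the statistical structure the analysis assumes — multi-site
  reference, scanner-by-wave clinical design, exponentially attenuating
  diagnosis effects, symptom coupling, MCAR/MNAR attrition — so the whole
  pipeline is testable without access to clinical data.

Cohorts live in a `CohortExperiment` (a `SummarizedExperiment`: ROIs ×
scans with covariates in `colData`), models in a `NormativeModelSet`.

## Worked example

```r
library(ctnorm)

cfg <- demoConfig(seed = 1)          # 218 CTRL / 79 SCZ, waves 0/1/10 y
run <- runPipeline(pipelineConfig(synthetic = cfg, outDir = "demo_out",
                                  adaptPerSite = 800, seed = 1))

## per-wave case-control effect size on the median deviation over the
## affected ROIs
sapply(0:2, function(w)
  groupEffectSizes(run$scored, w, "median_roi",
                   rois = rownames(run$scored)[1:20])$d)
#> [1] -1.575 -0.945 -0.129

## negative-extreme count test at baseline (post-QC sample)
subset(run$subjectCountTests, wave == 0 & tail == "neg")
#>   wave tail       U            p cl_effect n_scz n_ctrl
#> 1    0  neg 10048.5 4.96e-06      67.2       74    202

## conditional diagnosis effect per ROI, FDR across ROIs (first rows)
head(subset(run$deviationLME, term == "dx" & significant))
```

The generated study shows the qualitative signature the method is built
to expose: strong negative deviations in patients at baseline (d ≈ −1.6
on the affected-ROI median), attenuating by 12 months and nearly gone at
10 years, with the set of FDR-significant ROIs shrinking (16 → 6 → 0 in
the run above) while patients' PANSS scores decline.

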