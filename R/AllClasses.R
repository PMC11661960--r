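#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom stats coef cov lm lm.fit median optimize p.adjust pf
#'   plogis pnorm pt qlogis rbinom rnorm runif sd setNames
#'   t.test update var vcov complete.cases chisq.test
#' @importFrom utils combn read.csv write.csv head modifyList
NULL

#' Cohort of scans with regional cortical thickness
#'
#' `CohortExperiment` is a [SummarizedExperiment::SummarizedExperiment]
#' holding one column per scan and one row per cortical region (ROI). The
#' `"thickness"` assay carries thickness in millimetres; after scoring
#' against a normative model the object additionally carries `"deviation"`
#' (z-scores), `"predicted_mean"` and `"predictive_sd"` assays. Per-scan
#' covariates live in `colData`: `subject_id`, `site_id`, `group`
#' (`CTRL`/`SCZ`), `wave` (0-based index), `delay` (years since inclusion),
#' `age_at_scan`, `age_baseline`, `sex` (`F`/`M`, coded F=1/M=0 in all
#' design matrices), `qc_metric` (integer surface-quality metric) and the
#' four PANSS scores (`NA` for controls).
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

.cohort_covariates <- c("subject_id", "site_id", "group", "wave", "delay",
                        "age_at_scan", "age_baseline", "sex", "qc_metric",
                        "panss_total", "panss_positive", "panss_negative",
                        "panss_general")

setValidity("CohortExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.cohort_covariates, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (!"thickness" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'thickness' is required")
  if (!length(msg)) {
    if (any(cd$delay < 0, na.rm = TRUE))
      msg <- c(msg, "delay must be >= 0")
    if (any(abs(cd$age_at_scan - (cd$age_baseline + cd$delay)) > 1e-6,
            na.rm = TRUE))
      msg <- c(msg, "age_at_scan must equal age_baseline + delay")
    if (!all(cd$group %in% c("CTRL", "SCZ")))
      msg <- c(msg, "group must be CTRL or SCZ")
    if (!all(cd$sex %in% c("F", "M")))
      msg <- c(msg, "sex must be F or M")
    th <- SummarizedExperiment::assay(object, "thickness")
    if (any(!is.finite(th)) || any(th <= 0))
      msg <- c(msg, "thickness must be finite and > 0")
    key <- paste(cd$subject_id, cd$wave)
    if (anyDuplicated(key))
      msg <- c(msg, "each (subject, wave) pair must be unique")
    pans <- as.matrix(cd[, c("panss_total", "panss_positive",
                             "panss_negative", "panss_general")])
    if (any(!is.na(pans[cd$group == "CTRL", , drop = FALSE])))
      msg <- c(msg, "PANSS values must be missing for CTRL rows")
  }
  if (length(msg)) msg else TRUE
})

#' Per-ROI hierarchical normative models
#'
#' One fitted hierarchical Bayesian normative model per ROI: shared
#' hyperparameters (intercept/slope/log-noise means and between-batch SDs
#' plus a global female intercept offset) and batch-level parameters for
#' every (site, sex) cell, with the Gaussian posterior covariance of the
#' batch intercept and slope. Age is centred at the reference-training mean
#' (`ageCenter`), stored once and reused at transfer and scoring time.
#'
#' @slot hyper data.frame, one row per ROI: `roi`, `mu_a`, `tau_a`,
#'   `delta_f`, `mu_b`, `tau_b`, `mu_logsigma`, `tau_logsigma`.
#' @slot batches data.frame, one row per ROI x (site, sex) cell: `roi`,
#'   `site`, `sex`, `a`, `b`, `sigma`, `c_aa`, `c_ab`, `c_bb`, `n`.
#' @slot ageCenter numeric(1), years.
#' @slot fitMeta list: `backend`, `n_train`, `converged` (named logical per
#'   ROI), `min_batch_n`.
#' @slot varMode `"predictive"` (noise + parameter uncertainty, the default)
#'   or `"noise"` (noise SD only).
#' @export
setClass("NormativeModelSet",
  representation(hyper = "data.frame", batches = "data.frame",
                 ageCenter = "numeric", fitMeta = "list",
                 varMode = "character"))

setValidity("NormativeModelSet", function(object) {
  msg <- character()
  h <- object@hyper; b <- object@batches
  if (any(c(h$tau_a, h$tau_b, h$tau_logsigma) <= 0))
    msg <- c(msg, "hyper SDs (tau) must be > 0")
  if (nrow(b) && any(b$sigma <= 0))
    msg <- c(msg, "batch noise SD must be > 0")
  if (nrow(b) && any(b$c_aa < 0 | b$c_bb < 0 |
                     b$c_aa * b$c_bb - b$c_ab^2 < -1e-10))
    msg <- c(msg, "batch posterior covariance must be positive semi-definite")
  if (!is.finite(object@ageCenter))
    msg <- c(msg, "ageCenter must be finite")
  if (!object@varMode %in% c("predictive", "noise"))
    msg <- c(msg, "varMode must be 'predictive' or 'noise'")
  if (length(msg)) msg else TRUE
})

#' Generative specification for the synthetic cohort
#'
#' Full specification of the synthetic multi-site study: a cross-sectional
#' many-site healthy reference cohort and a 3-scanner longitudinal clinical
#' cohort with up to three waves, diagnosis effects on regional thickness
#' that attenuate exponentially with time, PANSS trajectories optionally
#' coupled to regional deviations, configurable attrition (MCAR or MNAR)
#' and a scalar surface-quality metric. All outputs are pure functions of
#' the configuration, including its `seed`.
#'
#' Defaults emulate the study design the package targets: 79 patients and
#' 218 controls at inclusion, waves near 0, 1 and 10 years, three clinical
#' scanners keyed to waves, a diagnosis effect of -0.5 z-units at baseline
#' on a diffuse 30-ROI subset attenuating with a 4-year time constant, PANSS
#' decreasing over time, and per-wave attrition of 15% then 65%.
#'
#' @slot nSitesRef,subjectsPerSiteRef reference-cohort size.
#' @slot nRois number of cortical regions (default 150).
#' @slot ageRangeRef reference age range, years.
#' @slot hyperIntercept,hyperSlope mean/SD (mm, mm/year) of the site-level
#'   intercept and age-slope distributions.
#' @slot hyperLogNoise mean/SD of log noise-SD.
#' @slot roiInterceptSd,roiSlopeSd,roiLogNoiseSd SD of the ROI-specific
#'   hyper-means drawn once per seed.
#' @slot sexOffsetSd SD (mm) of the per-ROI female intercept offset.
#' @slot subjectOffsetSd per-subject shared offset, as a fraction of the
#'   batch noise SD (within-subject ROI dependence; default 0.2).
#' @slot clinicalSites,nControlsClin,nPatientsClin clinical-cohort size.
#' @slot waveTimes nominal wave times in years, strictly increasing from 0.
#' @slot waveScannerMap list, one character vector of clinical site ids per
#'   wave: the scanners in use at that wave.
#' @slot delayJitterSd per-wave SD (years) of the realised visit time
#'   around `waveTimes`.
#' @slot ageClinMean,ageClinSd,patientAgeShift control baseline-age
#'   distribution and how much younger patients are on average.
#' @slot femaleFraction probability a subject is female.
#' @slot dxEffectBaseline baseline diagnosis effect in z-units (negative).
#' @slot dxAttenuationTau attenuation time constant, years.
#' @slot affectedRois integer indices of ROIs carrying the effect.
#' @slot panssBaseline named list `domain -> c(mean, sd)` at baseline.
#' @slot panssTimeSlope named numeric, points/year per domain (negative).
#' @slot panssNoiseSd occasion-level PANSS noise SD, points.
#' @slot panssCoupling named list `domain -> named numeric` mapping ROI
#'   index to points per z-unit.
#' @slot attritionMechanism `"MCAR"` or `"MNAR"`.
#' @slot attritionRate per-wave dropout probability (scalar or one value per
#'   follow-up wave).
#' @slot mnarCoef logistic coefficient of dropout on baseline median
#'   deviation (positive = more negative deviations drop out more).
#' @slot qcOutlierRate probability a scan fails surface quality control.
#' @slot seed integer master seed.
#' @export
setClass("SyntheticConfig",
  representation(
    nSitesRef = "numeric", subjectsPerSiteRef = "numeric", nRois = "numeric",
    ageRangeRef = "numeric",
    hyperIntercept = "numeric", hyperSlope = "numeric",
    hyperLogNoise = "numeric",
    roiInterceptSd = "numeric", roiSlopeSd = "numeric",
    roiLogNoiseSd = "numeric",
    sexOffsetSd = "numeric", subjectOffsetSd = "numeric",
    clinicalSites = "numeric", nControlsClin = "numeric",
    nPatientsClin = "numeric",
    waveTimes = "numeric", waveScannerMap = "list",
    delayJitterSd = "numeric",
    ageClinMean = "numeric", ageClinSd = "numeric",
    patientAgeShift = "numeric", femaleFraction = "numeric",
    dxEffectBaseline = "numeric", dxAttenuationTau = "numeric",
    affectedRois = "numeric",
    panssBaseline = "list", panssTimeSlope = "numeric",
    panssNoiseSd = "numeric", panssCoupling = "list",
    attritionMechanism = "character", attritionRate = "numeric",
    mnarCoef = "numeric",
    qcOutlierRate = "numeric", seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  cnt <- c(object@nSitesRef, object@subjectsPerSiteRef, object@nRois,
           object@clinicalSites, object@nControlsClin, object@nPatientsClin)
  if (any(cnt < 1)) msg <- c(msg, "all counts must be >= 1")
  wt <- object@waveTimes
  if (wt[1] != 0 || any(diff(wt) <= 0))
    msg <- c(msg, "waveTimes must be strictly increasing and start at 0")
  if (any(object@attritionRate < 0 | object@attritionRate >= 1))
    msg <- c(msg, "attrition rate must be in [0, 1)")
  sds <- c(object@hyperIntercept[2], object@hyperLogNoise[2])
  if (any(sds < 0)) msg <- c(msg, "hyperprior SDs must be >= 0")
  if (!object@attritionMechanism %in% c("MCAR", "MNAR"))
    msg <- c(msg, "attrition mechanism must be MCAR or MNAR")
  if (length(object@waveScannerMap) != length(wt))
    msg <- c(msg, "waveScannerMap needs one entry per wave")
  if (any(object@affectedRois < 1 | object@affectedRois > object@nRois))
    msg <- c(msg, "affectedRois out of range")
  if (object@qcOutlierRate < 0 || object@qcOutlierRate >= 1)
    msg <- c(msg, "qcOutlierRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Extreme-deviation summary
#'
#' Counts of extreme deviations (strict `|z| > threshold`, each tail
#' separately) per (subject, wave), and per (ROI, wave, group) the number
#' and proportion of scans with an extreme deviation.
#'
#' @slot subjectCounts data.frame: `subject_id`, `wave`, `group`,
#'   `n_neg_extreme`, `n_pos_extreme`, `n_rois_observed`.
#' @slot roiCounts data.frame: `roi`, `wave`, `group`, `n_neg_extreme`,
#'   `n_pos_extreme`, `n_scans`, `prop_neg_extreme`, `prop_pos_extreme`.
#' @slot threshold the z threshold used.
#' @export
setClass("ExtremeSummary",
  representation(subjectCounts = "data.frame", roiCounts = "data.frame",
                 threshold = "numeric"))

setValidity("ExtremeSummary", function(object) {
  msg <- character()
  s <- object@subjectCounts; r <- object@roiCounts
  if (nrow(s) && any(s$n_neg_extreme < 0 | s$n_pos_extreme < 0 |
                     s$n_neg_extreme > s$n_rois_observed |
                     s$n_pos_extreme > s$n_rois_observed))
    msg <- c(msg, "subject counts must lie in [0, n_rois_observed]")
  if (nrow(r) && any(r$prop_neg_extreme < 0 | r$prop_neg_extreme > 1 |
                     r$prop_pos_extreme < 0 | r$prop_pos_extreme > 1,
                     na.rm = TRUE))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (object@threshold <= 0) msg <- c(msg, "threshold must be > 0")
  if (length(msg)) msg else TRUE
})
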