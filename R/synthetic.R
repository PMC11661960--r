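#' @rdname SyntheticConfig-class
#' @param ... slot values overriding the defaults (see slot documentation).
#' @return A validated `SyntheticConfig`.
#' @examples
#' cfg <- SyntheticConfig(nSitesRef = 5, subjectsPerSiteRef = 50, nRois = 10)
#' @export
SyntheticConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    nSitesRef = 10, subjectsPerSiteRef = 100, nRois = 150,
    ageRangeRef = c(18, 65),
    hyperIntercept = c(mean = 2.5, sd = 0.08),
    hyperSlope = c(mean = -0.005, sd = 0.0015),
    hyperLogNoise = c(mean = log(0.12), sd = 0.15),
    roiInterceptSd = 0.25, roiSlopeSd = 0.001, roiLogNoiseSd = 0.1,
    sexOffsetSd = 0.02, subjectOffsetSd = 0.2,
    clinicalSites = 3, nControlsClin = 218, nPatientsClin = 79,
    waveTimes = c(0, 1, 10),
    waveScannerMap = list(),
    delayJitterSd = NULL,
    ageClinMean = 34, ageClinSd = 10, patientAgeShift = 6,
    femaleFraction = 0.42,
    dxEffectBaseline = -0.5, dxAttenuationTau = 4,
    affectedRois = NULL,
    panssBaseline = list(total = c(64, 14), positive = c(16, 5),
                         negative = c(16, 6), general = c(32, 8)),
    panssTimeSlope = c(total = -1.4, positive = -0.35, negative = -0.35,
                       general = -0.7),
    panssNoiseSd = 4,
    panssCoupling = list(),
    attritionMechanism = "MCAR", attritionRate = c(0.15, 0.65),
    mnarCoef = 0,
    qcOutlierRate = 0.05, seed = 1)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown SyntheticConfig field(s): ", paste(unknown, collapse = ", "))
  vals <- utils::modifyList(defaults, args)
  if (is.null(vals$affectedRois))
    vals$affectedRois <- seq_len(min(30, vals$nRois))
  if (is.null(vals$delayJitterSd))
    vals$delayJitterSd <- pmin(0.09 * vals$waveTimes, 0.9)
  if (!length(vals$waveScannerMap)) {
    sites <- .clin_site_ids(vals$clinicalSites)
    nw <- length(vals$waveTimes)
    vals$waveScannerMap <- if (vals$clinicalSites >= 3 && nw == 3)
      list(sites[1:2], sites[2], sites[3])
    else rep(list(sites), nw)
  }
  do.call(methods::new, c(list(Class = "SyntheticConfig"), vals))
}

.clin_site_ids <- function(k) paste0("clin", LETTERS[seq_len(k)])

#' Packaged demonstration configuration
#'
#' The default synthetic study used by the worked examples and the
#' acceptance script: a 10-site reference cohort (1000 controls), a
#' 3-scanner clinical cohort of 218 controls and 79 patients at waves
#' 0/1/10 years with attrition 15% then 65%, a -0.5 z-unit baseline
#' diagnosis effect on half of 40 ROIs attenuating with a 4-year time
#' constant, and PANSS total coupled at -3 points per z-unit to one
#' unaffected ROI. 40 ROIs keep the demonstration fast while preserving
#' the multiple-testing structure.
#'
#' @param seed master seed.
#' @param ... further overrides passed to [SyntheticConfig()].
#' @return A [SyntheticConfig-class].
#' @export
demoConfig <- function(seed = 1, ...) {
  base <- list(nSitesRef = 10, subjectsPerSiteRef = 100, nRois = 40,
               affectedRois = 1:20,
               panssCoupling = list(total = c("30" = -3)),
               seed = seed)
  do.call(SyntheticConfig, utils::modifyList(base, list(...)))
}

## ROI-level hyper-means (and the per-ROI female offset), drawn once per
## config seed so reference and clinical cohorts share the same anatomy.
.roiHypers <- function(config) {
  withr::with_seed(config@seed, {
    r <- config@nRois
    data.frame(
      roi = destrieuxLabels(r),
      A = config@hyperIntercept[1] + rnorm(r, 0, config@roiInterceptSd),
      B = config@hyperSlope[1] + rnorm(r, 0, config@roiSlopeSd),
      L = config@hyperLogNoise[1] + rnorm(r, 0, config@roiLogNoiseSd),
      delta_f = rnorm(r, 0, config@sexOffsetSd),
      stringsAsFactors = FALSE)
  })
}

## True batch-level parameters for a set of sites: intercept/slope per
## (site, sex, ROI), noise SD per (site, ROI) as sigma_s.
.drawBatchTruth <- function(config, hy, sites) {
  r <- config@nRois
  out <- list()
  for (s in sites) {
    siteL <- hy$L + rnorm(r, 0, config@hyperLogNoise[2])
    for (sex in c("F", "M")) {
      a <- hy$A + (sex == "F") * hy$delta_f +
        rnorm(r, 0, config@hyperIntercept[2])
      b <- hy$B + rnorm(r, 0, config@hyperSlope[2])
      out[[paste(s, sex)]] <- data.frame(
        site = s, sex = sex, roi = hy$roi, a = a, b = b,
        sigma = exp(siteL), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## thickness draw with a bounded resample of the noise for non-positive
## values (physically impossible at realistic settings, but guarded).
.drawThickness <- function(mu, sigma_mat, max_retry = 10) {
  eps <- matrix(rnorm(length(mu), 0, 1), nrow(mu)) * sigma_mat
  y <- mu + eps
  tries <- 0
  while (any(y <= 0) && tries < max_retry) {
    bad <- which(y <= 0)
    y[bad] <- mu[bad] + rnorm(length(bad)) * sigma_mat[bad]
    tries <- tries + 1
  }
  if (any(y <= 0))
    stop("non-positive thickness persisted after ", max_retry,
         " resampling rounds; check config scales (seed-dependent draw)")
  y
}

.qcDraw <- function(n, outlier_rate) {
  out <- rbinom(n, 1, outlier_rate) == 1
  qc <- integer(n)
  qc[!out] <- sample(0:5, sum(!out), replace = TRUE)
  qc[out] <- sample(6:20, sum(out), replace = TRUE)
  qc
}

#' Generate the cross-sectional healthy reference cohort
#'
#' Draws a many-site, controls-only reference cohort: per (site, sex) the
#' intercept and age-slope are drawn around ROI-specific hyper-means, the
#' noise SD per site is log-normal, and thickness is linear in age plus a
#' per-subject shared offset (within-subject ROI dependence) and Gaussian
#' noise. Deterministic given the config (reference draws use sub-seed
#' `seed + 1`; ROI hyper-means use `seed` itself and are shared with
#' [generateClinical()]).
#'
#' @param config a [SyntheticConfig-class].
#' @return A [CohortExperiment-class] (wave 0, `CTRL` only). The generative
#'   truth (ROI hyper-means and batch parameters) is kept in
#'   `S4Vectors::metadata()` under `"truth"`.
#' @export
generateReference <- function(config) {
  methods::validObject(config)
  hy <- .roiHypers(config)
  withr::with_seed(config@seed + 1, {
    sites <- sprintf("ref%02d", seq_len(config@nSitesRef))
    truth <- .drawBatchTruth(config, hy, sites)
    n <- config@nSitesRef * config@subjectsPerSiteRef
    scan <- data.frame(
      subject_id = sprintf("ref%05d", seq_len(n)),
      site_id = rep(sites, each = config@subjectsPerSiteRef),
      group = "CTRL", wave = 0L, delay = 0,
      age_at_scan = runif(n, config@ageRangeRef[1], config@ageRangeRef[2]),
      sex = ifelse(runif(n) < config@femaleFraction, "F", "M"),
      stringsAsFactors = FALSE)
    scan$age_baseline <- scan$age_at_scan
    scan$qc_metric <- sample(0:5, n, replace = TRUE)
    u <- rnorm(n)
    y <- .assembleThickness(config, truth, scan, u, dx_shift = NULL)
    ce <- CohortExperiment(y, scan)
    S4Vectors::metadata(ce)$truth <- list(roi = hy, batches = truth)
    ce
  })
}

## mu and noise for a block of scans given true batch parameters; applies
## an optional per-scan z-unit shift on the affected ROIs.
.assembleThickness <- function(config, truth, scan, u, dx_shift = NULL) {
  r <- config@nRois
  keys <- paste(truth$site, truth$sex)
  ukeys <- unique(keys)
  A <- matrix(vapply(ukeys, function(k) truth$a[keys == k], numeric(r)), r)
  B <- matrix(vapply(ukeys, function(k) truth$b[keys == k], numeric(r)), r)
  S <- matrix(vapply(ukeys, function(k) truth$sigma[keys == k], numeric(r)),
              r)
  j <- match(paste(scan$site_id, scan$sex), ukeys)
  mu <- A[, j, drop = FALSE] +
    B[, j, drop = FALSE] * rep(scan$age_at_scan, each = r)
  sig <- S[, j, drop = FALSE]
  mu <- mu + sig * (config@subjectOffsetSd * rep(u, each = r))
  if (!is.null(dx_shift)) {
    shift <- matrix(0, r, nrow(scan))
    shift[config@affectedRois, ] <-
      rep(dx_shift, each = length(config@affectedRois))
    mu <- mu + sig * shift
  }
  y <- .drawThickness(mu, sig)
  dimnames(y) <- list(truth$roi[keys == ukeys[1]], NULL)
  y
}

#' Generate the longitudinal clinical cohort
#'
#' Draws controls and patients scanned at up to `length(waveTimes)` waves on
#' scanners keyed to waves (`waveScannerMap`), with a patient effect on the
#' affected ROIs of `dxEffectBaseline * exp(-t / dxAttenuationTau)` z-units,
#' PANSS trajectories optionally coupled to regional deviations, per-wave
#' attrition (MCAR, or MNAR via a logistic dependence on the baseline
#' median deviation) and a quality-control metric with a configurable
#' outlier rate. Patients are on average `patientAgeShift` years younger
#' than controls. Deterministic given the config (sub-seed `seed + 2`).
#'
#' @param config a [SyntheticConfig-class].
#' @param subjectSeed optional separate seed for the subject-level draws
#'   (sampling, visits, noise, attrition). The scanners' true parameters
#'   depend only on `config@seed`, so fresh cohorts from the same scanners
#'   -- replicate experiments against one fitted model -- are obtained by
#'   varying `subjectSeed` alone. Default `config@seed + 2`.
#' @return A [CohortExperiment-class] with `CTRL` and `SCZ` scans across
#'   waves; generative truth in `S4Vectors::metadata()` under `"truth"`.
#' @export
generateClinical <- function(config, subjectSeed = NULL) {
  methods::validObject(config)
  if (config@ageClinMean + max(config@waveTimes) > 110)
    stop("waveTimes incompatible with the clinical age range")
  if (is.null(subjectSeed)) subjectSeed <- config@seed + 2
  hy <- .roiHypers(config)
  truth <- .clinicalTruth(config, hy)
  withr::with_seed(subjectSeed, {
    nC <- config@nControlsClin; nP <- config@nPatientsClin
    n <- nC + nP
    subj <- data.frame(
      subject_id = c(sprintf("ctrl%04d", seq_len(nC)),
                     sprintf("scz%04d", seq_len(nP))),
      group = rep(c("CTRL", "SCZ"), c(nC, nP)),
      sex = ifelse(runif(n) < config@femaleFraction, "F", "M"),
      stringsAsFactors = FALSE)
    subj$age_baseline <- pmax(16, ifelse(
      subj$group == "CTRL",
      rnorm(n, config@ageClinMean, config@ageClinSd),
      rnorm(n, config@ageClinMean - config@patientAgeShift,
            0.75 * config@ageClinSd)))
    subj$u <- rnorm(n)
    domains <- names(config@panssBaseline)
    pbase <- vapply(domains, function(d)
      rnorm(n, config@panssBaseline[[d]][1], config@panssBaseline[[d]][2]),
      numeric(n))

    nw <- length(config@waveTimes)
    rate <- rep_len(config@attritionRate, max(1, nw - 1))
    scans <- list(); zbase_med <- rep(NA_real_, n); clipped <- 0L
    retained <- rep(TRUE, n)
    for (w in seq_len(nw)) {
      t_nom <- config@waveTimes[w]
      if (w > 1) {
        p_drop <- rep(rate[w - 1], n)
        if (config@attritionMechanism == "MNAR" && config@mnarCoef != 0)
          p_drop <- plogis(qlogis(p_drop) - config@mnarCoef * zbase_med)
        retained <- retained & (runif(n) >= p_drop)
      }
      keep <- which(retained)
      if (!length(keep)) next
      sc <- subj[keep, c("subject_id", "group", "sex", "age_baseline")]
      pool <- config@waveScannerMap[[w]]
      sc$site_id <- if (length(pool) == 1) pool else
        sample(pool, length(keep), replace = TRUE)
      jit <- config@delayJitterSd[w]
      sc$delay <- if (w == 1) 0 else
        pmax(config@waveTimes[w - 1] + 0.1,
             t_nom + rnorm(length(keep), 0, jit))
      sc$wave <- w - 1L
      sc$age_at_scan <- sc$age_baseline + sc$delay
      sc$qc_metric <- .qcDraw(length(keep), config@qcOutlierRate)
      dx <- ifelse(sc$group == "SCZ",
                   config@dxEffectBaseline *
                     exp(-sc$delay / config@dxAttenuationTau), 0)
      y <- .assembleThickness(config, truth, sc, subj$u[keep], dx_shift = dx)
      ## generative z against the true normative surface (no dx shift)
      keys <- paste(truth$site, truth$sex)
      ukeys <- unique(keys)
      j <- match(paste(sc$site_id, sc$sex), ukeys)
      r <- config@nRois
      A <- matrix(vapply(ukeys, function(k) truth$a[keys == k],
                         numeric(r)), r)
      B <- matrix(vapply(ukeys, function(k) truth$b[keys == k],
                         numeric(r)), r)
      S <- matrix(vapply(ukeys, function(k) truth$sigma[keys == k],
                         numeric(r)), r)
      z <- (y - (A[, j, drop = FALSE] +
                 B[, j, drop = FALSE] * rep(sc$age_at_scan, each = r))) /
        S[, j, drop = FALSE]
      if (w == 1) zbase_med[keep] <- apply(z, 2, median)
      for (d in domains) {
        val <- rep(NA_real_, length(keep))
        is_p <- sc$group == "SCZ"
        coup <- config@panssCoupling[[d]]
        cz <- if (length(coup))
          colSums(z[as.integer(names(coup)), , drop = FALSE] * coup) else 0
        val[is_p] <- (pbase[keep, d] + config@panssTimeSlope[[d]] * sc$delay +
                      cz + rnorm(length(keep), 0, config@panssNoiseSd))[is_p]
        floorv <- c(total = 30, positive = 7, negative = 7, general = 16)[d]
        if (!is.na(floorv)) {
          clipped <- clipped + sum(val < floorv, na.rm = TRUE)
          val <- pmax(val, floorv)
        }
        sc[[paste0("panss_", d)]] <- val
      }
      scans[[w]] <- list(scan = sc, y = y)
    }
    scan <- do.call(rbind, lapply(scans, `[[`, "scan"))
    y <- do.call(cbind, lapply(scans, `[[`, "y"))
    ce <- CohortExperiment(y, scan[, c(.cohort_covariates)])
    S4Vectors::metadata(ce)$truth <- list(
      roi = hy, batches = truth,
      dx_effect = config@dxEffectBaseline, tau = config@dxAttenuationTau,
      affected = config@affectedRois, subject_offset = subj$u)
    S4Vectors::metadata(ce)$panss_clipped <- clipped
    if (clipped > 0)
      message("PANSS floor clipping applied to ", clipped, " value(s)")
    ce
  })
}

## True clinical-scanner parameters depend only on the config seed
## (sub-seed seed + 3), so held-out adaptation controls and the
## longitudinal cohort are scanned on the same scanners.
.clinicalTruth <- function(config, hy = .roiHypers(config)) {
  withr::with_seed(config@seed + 3,
    .drawBatchTruth(config, hy, .clin_site_ids(config@clinicalSites)))
}

#' Generate held-out adaptation controls
#'
#' Cross-sectional healthy controls scanned on the clinical scanners,
#' drawn from the same true scanner parameters as [generateClinical()]
#' (which depend only on the config seed) but from an independent subject
#' stream: the held-out local controls used to transfer the reference
#' normative models to the unseen scanners.
#'
#' @param config a [SyntheticConfig-class].
#' @param nPerSite controls per clinical site.
#' @param subseed offset added to the config seed for the subject draws
#'   (default 7; any value gives subjects independent of the longitudinal
#'   cohort, which uses offset 2).
#' @return A [CohortExperiment-class] (wave 0, `CTRL` only).
#' @export
generateAdaptation <- function(config, nPerSite = 250, subseed = 7) {
  methods::validObject(config)
  hy <- .roiHypers(config)
  truth <- .clinicalTruth(config, hy)
  withr::with_seed(config@seed + subseed, {
    sites <- .clin_site_ids(config@clinicalSites)
    n <- nPerSite * length(sites)
    scan <- data.frame(
      subject_id = sprintf("adapt%05d", seq_len(n)),
      site_id = rep(sites, each = nPerSite),
      group = "CTRL", wave = 0L, delay = 0,
      age_at_scan = pmax(16, rnorm(n, config@ageClinMean, config@ageClinSd)),
      sex = ifelse(runif(n) < config@femaleFraction, "F", "M"),
      stringsAsFactors = FALSE)
    scan$age_baseline <- scan$age_at_scan
    scan$qc_metric <- sample(0:5, n, replace = TRUE)
    y <- .assembleThickness(config, truth, scan, rnorm(n))
    ce <- CohortExperiment(y, scan)
    S4Vectors::metadata(ce)$truth <- list(roi = hy, batches = truth)
    ce
  })
}

#' Stratified train/validation split of a reference cohort
#'
#' Splits subjects within each site, keeping per-site training fractions
#' within one subject of the target. A site with a single subject sends it
#' to the training set with a warning.
#'
#' @param x a [CohortExperiment-class].
#' @param trainFraction proportion of each site's subjects for training.
#' @param seed integer seed for the split.
#' @return list with elements `train` and `validation`.
#' @export
splitReference <- function(x, trainFraction = 0.95, seed = 1) {
  stopifnot(trainFraction > 0, trainFraction <= 1)
  cd <- scanData(x)
  subj <- unique(cd[, c("subject_id", "site_id")])
  withr::with_seed(seed, {
    train_ids <- unlist(lapply(split(subj$subject_id, subj$site_id),
      function(ids) {
        if (length(ids) == 1) {
          warning("site with a single subject: assigned to train")
          return(ids)
        }
        k <- round(trainFraction * length(ids))
        k <- min(max(k, 1), length(ids))
        sample(ids, k)
      }), use.names = FALSE)
  })
  keep <- cd$subject_id %in% train_ids
  list(train = x[, keep], validation = x[, !keep])
}
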