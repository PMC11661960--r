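#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]: either a
#' [SyntheticConfig-class] to simulate from, or paths to reference and
#' clinical scan tables, plus the analysis thresholds. The master `seed`
#' fans out to per-stage sub-seeds by a fixed offset scheme (simulate uses
#' the synthetic config's own seed; the reference split uses `seed + 11`),
#' so stages are individually reproducible.
#'
#' @param synthetic a `SyntheticConfig`, or `NULL` to read tables.
#' @param referencePath,clinicalPath CSV paths (used when `synthetic` is
#'   `NULL`).
#' @param outDir output directory for stage CSVs.
#' @param qcThreshold surface-quality cut (scans above it are removed).
#' @param extremeThreshold z threshold for extreme deviations.
#' @param fdrAlpha FDR level for all BH families.
#' @param trainFraction reference train/validation split fraction.
#' @param adaptPerSite held-out controls per clinical site used for the
#'   transfer step.
#' @param reml REML (default) or ML for all mixed models.
#' @param seed master seed.
#' @return validated list of class `"ctnormPipelineConfig"`.
#' @export
pipelineConfig <- function(synthetic = NULL, referencePath = NULL,
                           clinicalPath = NULL, outDir = tempdir(),
                           qcThreshold = 5, extremeThreshold = 2,
                           fdrAlpha = 0.05, trainFraction = 0.95,
                           adaptPerSite = 250, reml = TRUE, seed = 1) {
  stopifnot(qcThreshold > 0, extremeThreshold > 0,
            fdrAlpha > 0, fdrAlpha < 1)
  if (is.null(synthetic) &&
      (is.null(referencePath) || is.null(clinicalPath)))
    stop("provide either a SyntheticConfig or reference/clinical paths")
  structure(list(synthetic = synthetic, referencePath = referencePath,
                 clinicalPath = clinicalPath, outDir = outDir,
                 qcThreshold = qcThreshold,
                 extremeThreshold = extremeThreshold, fdrAlpha = fdrAlpha,
                 trainFraction = trainFraction,
                 adaptPerSite = adaptPerSite, reml = reml, seed = seed),
            class = "ctnormPipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> QC -> reference split -> normative
#' fit -> transfer to the clinical scanners -> deviation scoring ->
#' calibration -> extreme-deviation statistics -> the three mixed-model
#' analyses -> attrition diagnostics -> demographics, writing each stage's
#' tidy output as CSV under `config$outDir` and returning a manifest with
#' per-stage row accounting and output-file digests. Deterministic given
#' the configuration.
#'
#' When the clinical table carries no PANSS values, the symptom-trajectory
#' and symptom-association stages are skipped with a warning.
#'
#' @param config a `"ctnormPipelineConfig"` from [pipelineConfig()].
#' @return list with all stage outputs and `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "ctnormPipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  files <- character()
  log_stage <- function(name, n_in, n_out, note = "") {
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out,
                                     note = note)
  }
  emit <- function(df, name) {
    p <- file.path(config$outDir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE, na = "")
    files <<- c(files, p)
  }

  ## stage: acquire data
  if (!is.null(config$synthetic)) {
    ref <- generateReference(config$synthetic)
    clin <- generateClinical(config$synthetic)
    log_stage("simulate", NA, ncol(ref) + ncol(clin))
  } else {
    ref <- readScanTable(config$referencePath)
    clin <- readScanTable(config$clinicalPath)
    log_stage("read", NA, ncol(ref) + ncol(clin))
  }

  ## stage: QC (clinical scans; the reference pool is assumed curated)
  qc <- qcFilter(clin, config$qcThreshold)
  clin <- qc$kept
  log_stage("qc", qc$n_kept + qc$n_removed, qc$n_kept,
            paste(qc$n_removed, "scans removed"))

  ## stage: reference split and normative fit
  sp <- splitReference(ref, config$trainFraction, seed = config$seed + 11)
  model <- fitReference(sp$train)
  log_stage("fit_reference", ncol(ref), ncol(sp$train),
            paste("backend", fitMeta(model)$backend))

  ## stage: transfer to clinical scanners on held-out local controls.
  ## Adaptation controls are simulated wave-0 controls from the clinical
  ## scanners when simulating; when reading tables, clinical baseline
  ## controls are reused as the adaptation set.
  clin_sites <- unique(scanData(clin)$site_id)
  if (!is.null(config$synthetic)) {
    adapt <- generateAdaptation(config$synthetic, config$adaptPerSite)
    adapt <- adapt[, scanData(adapt)$site_id %in% clin_sites]
  } else {
    cdc <- scanData(clin)
    adapt <- clin[, cdc$group == "CTRL" & cdc$wave == 0]
  }
  model <- transferModel(model, adapt, clin_sites)
  log_stage("transfer", ncol(adapt), nrow(batchParameters(model)))
  emit(hyperParameters(model), "model_hyper")
  emit(batchParameters(model), "model_batches")

  ## stage: scoring + calibration. Calibration uses held-out controls on
  ## the clinical scanners (post-transfer, the property that matters for
  ## cross-scanner comparability); for table input it falls back to the
  ## reference validation split when large enough.
  scored <- scoreDeviations(model, clin)
  calib <- NULL
  if (!is.null(config$synthetic)) {
    heldout <- generateAdaptation(config$synthetic,
                                  nPerSite = max(20, config$adaptPerSite),
                                  subseed = 13)
    calib <- calibrationReport(scoreDeviations(model, heldout))
  } else if (ncol(sp$validation) >= 30) {
    val <- sp$validation[, scanData(sp$validation)$site_id %in%
                           batchParameters(model)$site]
    calib <- calibrationReport(scoreDeviations(model, val))
  }
  log_stage("score", ncol(clin), ncol(scored),
            if (is.null(calib)) "calibration skipped: too few controls"
            else paste(sum(calib$pass), "of", nrow(calib), "ROIs pass"))
  emit(deviationTable(scored), "deviations")
  if (!is.null(calib)) emit(calib, "calibration")

  ## stage: extreme deviations
  ext <- countExtremes(scored, config$extremeThreshold)
  waves <- sort(unique(scanData(scored)$wave))
  roi_tests <- do.call(rbind, lapply(waves, function(w) {
    cbind(wave = w, roiExtremeTest(ext, w, alpha = config$fdrAlpha))
  }))
  cnt_tests <- do.call(rbind, lapply(waves, function(w) {
    do.call(rbind, lapply(c("neg", "pos"), function(tl) {
      r <- subjectCountTest(ext, w, tl)
      data.frame(wave = w, tail = tl, U = r$U, p = r$p,
                 cl_effect = r$cl_effect, n_scz = r$n_scz,
                 n_ctrl = r$n_ctrl)
    }))
  }))
  dmed <- do.call(rbind, lapply(waves, function(w)
    cbind(wave = w, groupEffectSizes(scored, w))))
  log_stage("extremes", ncol(scored), nrow(roi_tests))
  emit(subjectCounts(ext), "extreme_subject_counts")
  emit(roi_tests, "extreme_roi_tests")
  emit(cnt_tests, "extreme_count_tests")
  emit(dmed, "effect_sizes_median")

  ## stage: mixed models (ROIs whose normative fit did not converge are
  ## excluded from the FDR families)
  rois_ok <- intersect(rownames(scored),
                       names(which(fitMeta(model)$converged)))
  dev_lme <- roiDeviationLME(scored, rois = rois_ok,
                             alpha = config$fdrAlpha, reml = config$reml)
  log_stage("deviation_lme", ncol(scored), nrow(dev_lme))
  emit(dev_lme, "deviation_lme")

  has_panss <- any(!is.na(scanData(clin)$panss_total))
  panss_time <- NULL; panss_dev <- NULL
  if (has_panss) {
    panss_time <- panssTimeLME(scored, reml = config$reml)
    panss_dev <- panssDeviationLME(scored, rois = rois_ok,
                                   alpha = config$fdrAlpha,
                                   reml = config$reml)
    log_stage("panss_lme", sum(scanData(clin)$group == "SCZ"),
              nrow(panss_dev))
    emit(panss_time$coef, "panss_time_lme")
    emit(panss_time$contrasts, "panss_wave_contrasts")
    emit(panss_dev, "panss_deviation_lme")
  } else {
    warning("no PANSS values: symptom-model stages skipped")
    log_stage("panss_lme", 0, 0, "skipped: no PANSS values")
  }

  ## stage: attrition diagnostics
  cdn <- scanData(scored)
  base <- cdn[cdn$wave == 0, ]
  z <- deviations(scored)[, cdn$wave == 0, drop = FALSE]
  base$median_dev <- apply(z, 2, median, na.rm = TRUE)
  last_wave <- max(cdn$wave)
  completers <- unique(cdn$subject_id[cdn$wave == last_wave])
  att <- NULL
  scz_base <- base[base$group == "SCZ", ]
  if (sum(scz_base$subject_id %in% completers) >= 2 &&
      sum(!scz_base$subject_id %in% completers) >= 2) {
    vars <- c("median_dev",
              if (has_panss) c("panss_total", "panss_positive",
                               "panss_negative", "panss_general"))
    att <- attritionTests(scz_base, completers, vars)
    emit(att$tests, "attrition_tests")
  }
  demo <- demographicsTable(scored)
  emit(demo, "demographics")
  log_stage("attrition", nrow(base),
            if (is.null(att)) 0 else nrow(att$tests))

  manifest$files <- data.frame(path = files,
                               md5 = unname(tools::md5sum(files)),
                               row.names = NULL)
  list(model = model, scored = scored, calibration = calib,
       extremes = ext, roiExtremeTests = roi_tests,
       subjectCountTests = cnt_tests, medianEffectSizes = dmed,
       deviationLME = dev_lme, panssTime = panss_time,
       panssDeviation = panss_dev, attrition = att, demographics = demo,
       qcLog = qc$log, manifest = manifest)
}
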