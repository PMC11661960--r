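#' Construct a CohortExperiment
#'
#' @param thickness numeric matrix, ROIs x scans, in mm; rownames are ROI
#'   labels.
#' @param scanData data.frame of per-scan covariates (see
#'   [CohortExperiment-class]), one row per column of `thickness`.
#' @return A [CohortExperiment-class].
#' @examples
#' cfg <- SyntheticConfig(nSitesRef = 3, subjectsPerSiteRef = 20, nRois = 4)
#' ref <- generateReference(cfg)
#' ref
#' @export
CohortExperiment <- function(thickness, scanData) {
  thickness <- as.matrix(thickness)
  scanData <- as.data.frame(scanData)
  for (col in c("panss_total", "panss_positive", "panss_negative",
                "panss_general"))
    if (is.null(scanData[[col]])) scanData[[col]] <- NA_real_
  if (is.null(colnames(thickness)))
    colnames(thickness) <- paste(scanData$subject_id, scanData$wave,
                                 sep = "_w")
  rownames(scanData) <- colnames(thickness)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(thickness = thickness),
    colData = S4Vectors::DataFrame(scanData))
  methods::new("CohortExperiment", se)
}

#' @describeIn CohortExperiment Per-scan covariates as a base data.frame.
#' @param x,object a `CohortExperiment`.
#' @export
scanData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn CohortExperiment ROI x scan thickness matrix (mm).
#' @export
thickness <- function(x) SummarizedExperiment::assay(x, "thickness")

#' @describeIn CohortExperiment ROI x scan deviation z-score matrix (present
#'   after [scoreDeviations()]).
#' @export
deviations <- function(x) {
  if (!"deviation" %in% SummarizedExperiment::assayNames(x))
    stop("no 'deviation' assay: score the cohort with scoreDeviations() first")
  SummarizedExperiment::assay(x, "deviation")
}

#' @describeIn CohortExperiment ROI labels.
#' @export
roiNames <- function(x) rownames(x)

setMethod("show", "CohortExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("CohortExperiment:", nrow(object), "ROIs x", ncol(object), "scans\n")
  cat("  subjects:", length(unique(cd$subject_id)),
      " sites:", paste(sort(unique(cd$site_id)), collapse = ", "), "\n")
  cat("  groups:", paste(names(table(cd$group)), table(cd$group),
                         sep = "=", collapse = " "),
      " waves:", paste(sort(unique(cd$wave)), collapse = ", "), "\n")
  cat("  assays:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
})

#' Long-format deviation table
#'
#' Flattens the deviation assays of a scored cohort into the long format
#' used for export: one row per scan x ROI with the z-score, the normative
#' predicted mean and the predictive SD.
#'
#' @param x a scored [CohortExperiment-class].
#' @return data.frame with columns `subject_id`, `wave`, `roi_id`, `z`,
#'   `predicted_mean`, `predictive_sd`.
#' @export
deviationTable <- function(x) {
  z <- deviations(x)
  cd <- scanData(x)
  data.frame(
    subject_id = rep(cd$subject_id, each = nrow(z)),
    wave = rep(cd$wave, each = nrow(z)),
    roi_id = rep(rownames(z), times = ncol(z)),
    z = as.vector(z),
    predicted_mean = as.vector(SummarizedExperiment::assay(x, "predicted_mean")),
    predictive_sd = as.vector(SummarizedExperiment::assay(x, "predictive_sd")),
    stringsAsFactors = FALSE)
}

#' Packaged cortical parcellation labels
#'
#' The 150 region labels used by default for ROI columns: the standard
#' Destrieux surface-parcellation labels (74 per hemisphere) plus the medial
#' wall, prefixed `lh_` / `rh_`.
#'
#' @param n optionally return only the first `n` labels.
#' @return character vector of labels.
#' @export
destrieuxLabels <- function(n = NULL) {
  path <- system.file("extdata", "destrieux_labels.txt", package = "ctnorm")
  labs <- readLines(path)
  if (!is.null(n)) {
    if (n <= length(labs)) labs <- labs[seq_len(n)]
    else labs <- c(labs, sprintf("ROI_%03d", seq.int(length(labs) + 1L, n)))
  }
  labs
}

.scan_table_cols <- function(rois)
  c(.cohort_covariates, rois)

#' Read / write scan tables
#'
#' Long-format CSV interchange for cohorts: one row per scan, a fixed
#' covariate column order (`subject_id`, `site_id`, `group`, `wave`,
#' `delay`, `age_at_scan`, `age_baseline`, `sex`, `qc_metric`, the four
#' PANSS columns) followed by one column per ROI named by its parcellation
#' label. Missing PANSS values are written as empty fields and read back as
#' `NA`. `writeScanTable()` then `readScanTable()` is an identity on valid
#' cohorts.
#'
#' @param x a [CohortExperiment-class].
#' @param path CSV file path.
#' @return `readScanTable()` returns a `CohortExperiment`;
#'   `writeScanTable()` returns `path` invisibly.
#' @export
writeScanTable <- function(x, path) {
  df <- cbind(scanData(x)[, .cohort_covariates],
              as.data.frame(t(thickness(x))))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeScanTable
#' @export
readScanTable <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  header <- gsub('^"|"$', "", header)
  miss <- setdiff(.cohort_covariates, header)
  if (length(miss))
    stop("schema error in ", path, ": missing required column(s) ",
         paste(miss, collapse = ", "))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rois <- setdiff(colnames(df), .cohort_covariates)
  if (!length(rois))
    stop("schema error in ", path, ": no ROI columns found")
  known <- destrieuxLabels()
  unknown <- setdiff(rois, c(known, sprintf("ROI_%03d", 1:999)))
  if (length(unknown))
    warning("ROI columns not in the packaged parcellation label list: ",
            paste(head(unknown, 10), collapse = ", "),
            if (length(unknown) > 10) ", ...")
  bad <- which(!complete.cases(df[, c("subject_id", "site_id", "group",
                                      "wave", "delay", "age_at_scan",
                                      "age_baseline", "sex", "qc_metric")]))
  if (length(bad))
    stop("schema error in ", path, ": missing covariate values in row(s) ",
         paste(head(bad, 10), collapse = ", "))
  th <- t(as.matrix(df[, rois, drop = FALSE]))
  rownames(th) <- rois
  CohortExperiment(th, df[, .cohort_covariates])
}
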