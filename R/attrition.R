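#' Quality-control filter
#'
#' Removes scans whose surface-quality metric exceeds the threshold
#' (strictly greater than; the conventional cut is 5). Returns both parts
#' and a removal log with counts per site and wave.
#'
#' @param x a [CohortExperiment-class].
#' @param threshold integer QC cut, default 5.
#' @return list: `kept`, `removed` (both `CohortExperiment`), `log`
#'   (data.frame of removals per site x wave).
#' @export
qcFilter <- function(x, threshold = 5) {
  cd <- scanData(x)
  bad <- cd$qc_metric > threshold
  if (any(bad)) {
    log <- as.data.frame(table(site_id = cd$site_id[bad],
                               wave = cd$wave[bad]),
                         stringsAsFactors = FALSE)
    names(log)[3] <- "n_removed"
  } else {
    log <- data.frame(site_id = character(0), wave = integer(0),
                      n_removed = integer(0))
  }
  list(kept = x[, !bad], removed = x[, bad], log = log,
       n_removed = sum(bad), n_kept = sum(!bad))
}

#' Attrition-bias tests
#'
#' Compares baseline variables between completers and dropouts with a
#' two-sample pooled-variance t-test per variable (Welch behind a switch).
#' Registry-style count variables can additionally be tested with a
#' Mann-Whitney rank test as a sensitivity output. Constant variables are
#' flagged and their p omitted. A logistic model of completion on all
#' variables jointly is returned as a further sensitivity output.
#'
#' @param baseline data.frame of one row per subject at baseline,
#'   including `subject_id` and the comparison variables.
#' @param completerIds subject ids of completers.
#' @param variables column names to compare.
#' @param countVariables subset of `variables` to also rank-test.
#' @param welch use the Welch t-test instead of pooled variance.
#' @return list of class `"ctnormAttrition"`: `tests` (variable,
#'   mean_completers, mean_dropouts, t, df, p, p_rank), `n_completers`,
#'   `n_dropouts`, `logistic` (glm coefficient table).
#' @export
attritionTests <- function(baseline, completerIds, variables,
                           countVariables = character(), welch = FALSE) {
  comp <- baseline$subject_id %in% completerIds
  if (sum(comp) < 2 || sum(!comp) < 2)
    stop("need at least 2 subjects per attrition group")
  rows <- lapply(variables, function(v) {
    a <- baseline[[v]][comp]; b <- baseline[[v]][!comp]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    out <- data.frame(variable = v, mean_completers = mean(a),
                      mean_dropouts = mean(b), t = NA_real_, df = NA_real_,
                      p = NA_real_, p_rank = NA_real_, flagged = FALSE)
    if (sd(c(a, b)) == 0) {
      out$flagged <- TRUE
      return(out)
    }
    tt <- t.test(a, b, var.equal = !welch)
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
    if (v %in% countVariables)
      out$p_rank <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    out
  })
  glm_dat <- baseline[, variables, drop = FALSE]
  glm_dat$completer <- as.numeric(comp)
  lg <- tryCatch(suppressWarnings({
    g <- stats::glm(completer ~ ., data = glm_dat,
                    family = stats::binomial())
    as.data.frame(summary(g)$coefficients)
  }), error = function(e) NULL)
  structure(list(tests = do.call(rbind, rows), n_completers = sum(comp),
                 n_dropouts = sum(!comp), logistic = lg),
            class = "ctnormAttrition")
}

#' @export
print.ctnormAttrition <- function(x, ...) {
  cat("Attrition comparison:", x$n_completers, "completers vs",
      x$n_dropouts, "dropouts\n")
  print(x$tests, digits = 4)
  invisible(x)
}

#' One-way ANOVA F from printed summary statistics
#'
#' Reconstructs the one-way ANOVA F statistic from group means, SDs and
#' sizes: between-group sum of squares from the means and sizes,
#' within-group from the SDs. For two groups F equals the square of the
#' pooled-variance t statistic.
#'
#' @param means,sds,ns numeric vectors, one entry per group.
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
anovaFromSummary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(k >= 2, length(sds) == k, length(ns) == k,
            all(ns >= 2), all(sds > 0))
  gm <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1; df2 <- sum(ns) - k
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

## half-up rounding to integer percent, the printed-table convention
.pct_half_up <- function(x) floor(100 * x + 0.5)

#' Integer composition percentages
#'
#' Count-over-total percentages rounded half-up to integers, the
#' convention used in printed demographic tables (e.g. 57 of 79 gives
#' 72\%).
#'
#' @param counts numeric counts.
#' @param total denominator (default `sum(counts)`).
#' @return integer percentages.
#' @export
compositionPercent <- function(counts, total = sum(counts)) {
  .pct_half_up(counts / total)
}

#' Demographics summary table
#'
#' Per wave and group: sample size, age mean \[SD\], percent female
#' (half-up integer rounding) and for patients the PANSS total mean
#' \[SD\] -- the layout of a standard longitudinal demographics table.
#'
#' @param x a [CohortExperiment-class].
#' @return data.frame, one row per (wave, group).
#' @export
demographicsTable <- function(x) {
  cd <- scanData(x)
  cells <- expand.grid(wave = sort(unique(cd$wave)),
                       group = c("CTRL", "SCZ"), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- cd$wave == cells$wave[i] & cd$group == cells$group[i]
    d <- cd[sel, ]
    if (!nrow(d))
      return(data.frame(wave = cells$wave[i], group = cells$group[i],
                        n = 0L, age_mean = NA_real_, age_sd = NA_real_,
                        pct_female = NA_integer_, panss_mean = NA_real_,
                        panss_sd = NA_real_))
    data.frame(wave = cells$wave[i], group = cells$group[i], n = nrow(d),
               age_mean = mean(d$age_at_scan), age_sd = sd(d$age_at_scan),
               pct_female = .pct_half_up(mean(d$sex == "F")),
               panss_mean = if (all(is.na(d$panss_total))) NA_real_
                            else mean(d$panss_total, na.rm = TRUE),
               panss_sd = if (all(is.na(d$panss_total))) NA_real_
                          else sd(d$panss_total, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
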