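#' Count extreme deviations
#'
#' Tallies extreme deviations at a strict threshold (`z < -threshold` and
#' `z > threshold`, each tail separately): per (subject, wave) the number
#' of extreme ROIs, and per (ROI, wave, group) the count and proportion of
#' scans with an extreme deviation. Missing z-scores are excluded from both
#' numerator and denominator; denominators are reported.
#'
#' @param x a scored [CohortExperiment-class].
#' @param threshold z threshold, default 2.0.
#' @return An [ExtremeSummary-class].
#' @export
countExtremes <- function(x, threshold = 2) {
  stopifnot(threshold > 0)
  z <- deviations(x)
  cd <- scanData(x)
  neg <- z < -threshold
  pos <- z > threshold
  subjectCounts <- data.frame(
    subject_id = cd$subject_id, wave = cd$wave, group = cd$group,
    n_neg_extreme = colSums(neg, na.rm = TRUE),
    n_pos_extreme = colSums(pos, na.rm = TRUE),
    n_rois_observed = colSums(!is.na(z)),
    row.names = NULL, stringsAsFactors = FALSE)
  cell <- paste(cd$wave, cd$group)
  roi_l <- lapply(unique(cell), function(k) {
    cols <- cell == k
    data.frame(
      roi = rownames(z),
      wave = cd$wave[cols][1], group = cd$group[cols][1],
      n_neg_extreme = rowSums(neg[, cols, drop = FALSE], na.rm = TRUE),
      n_pos_extreme = rowSums(pos[, cols, drop = FALSE], na.rm = TRUE),
      n_scans = rowSums(!is.na(z[, cols, drop = FALSE])),
      row.names = NULL, stringsAsFactors = FALSE)
  })
  roiCounts <- do.call(rbind, roi_l)
  roiCounts$prop_neg_extreme <- roiCounts$n_neg_extreme / roiCounts$n_scans
  roiCounts$prop_pos_extreme <- roiCounts$n_pos_extreme / roiCounts$n_scans
  methods::new("ExtremeSummary", subjectCounts = subjectCounts,
               roiCounts = roiCounts, threshold = threshold)
}

#' @describeIn countExtremes Per-subject extreme counts.
#' @param summary an `ExtremeSummary`.
#' @export
subjectCounts <- function(summary) summary@subjectCounts

#' @describeIn countExtremes Per-ROI extreme counts and proportions.
#' @export
roiCounts <- function(summary) summary@roiCounts

setMethod("show", "ExtremeSummary", function(object) {
  cat("ExtremeSummary: |z| >", object@threshold, "\n")
  cat(" ", nrow(object@subjectCounts), "scans,",
      length(unique(object@roiCounts$roi)), "ROIs,",
      "waves:", paste(sort(unique(object@subjectCounts$wave)),
                      collapse = ", "), "\n")
})

#' Per-ROI case-control test on extreme-deviation proportions
#'
#' For each ROI at one wave, a 2x2 contingency table (extreme vs not x
#' SCZ vs CTRL) tested with a Pearson chi-square (no continuity correction
#' by default) and summarised by Cramer's V = sqrt(chi2 / n). P-values are
#' BH-adjusted across ROIs; both the raw and adjusted values are returned.
#' Tables with a zero margin are flagged and assigned p = 1, V = 0.
#'
#' @param summary an [ExtremeSummary-class].
#' @param wave wave index to test.
#' @param tail `"neg"` (default) or `"pos"`.
#' @param alpha FDR level, default 0.05.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return data.frame: `roi`, `chi2`, `p`, `q`, `cramers_v`, `significant`,
#'   `flagged`.
#' @export
roiExtremeTest <- function(summary, wave, tail = c("neg", "pos"),
                           alpha = 0.05, correct = FALSE) {
  tail <- match.arg(tail)
  rc <- summary@roiCounts
  rc <- rc[rc$wave == wave, ]
  if (length(unique(rc$group)) < 2)
    stop("both groups must be present at wave ", wave)
  cnt <- paste0("n_", tail, "_extreme")
  out <- do.call(rbind, lapply(split(rc, rc$roi), function(d) {
    scz <- d[d$group == "SCZ", ]; ctl <- d[d$group == "CTRL", ]
    tab <- rbind(c(scz[[cnt]], scz$n_scans - scz[[cnt]]),
                 c(ctl[[cnt]], ctl$n_scans - ctl[[cnt]]))
    n <- sum(tab)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      data.frame(roi = d$roi[1], chi2 = 0, p = 1, cramers_v = 0,
                 flagged = TRUE)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = correct))
      data.frame(roi = d$roi[1], chi2 = unname(ct$statistic),
                 p = unname(ct$p.value),
                 cramers_v = sqrt(unname(ct$statistic) / n), flagged = FALSE)
    }
  }))
  fdr <- bhFDR(out$p, alpha)
  out$q <- fdr$q
  out$significant <- fdr$reject
  rownames(out) <- NULL
  out[, c("roi", "chi2", "p", "q", "cramers_v", "significant", "flagged")]
}

## Mann-Whitney U with midranks: U = #pairs(a > b) + 0.5 #ties, oriented
## so the first sample is `a`.
.mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Case-control test on per-subject extreme counts
#'
#' Mann-Whitney U test of the number of extreme deviations per subject
#' (one tail at a time) between patients and controls at one wave, with
#' midranks and a tie-corrected normal approximation; when both groups
#' have at most `exactMax` subjects the null distribution is enumerated
#' exactly over all group assignments of the observed counts. The
#' common-language (CL) effect size is U / (n1 n2) as a percentage,
#' oriented as P(SCZ count > CTRL count) + 0.5 P(tie), so values above 50%
#' mean patients have more extreme deviations.
#'
#' @param summary an [ExtremeSummary-class].
#' @param wave wave index.
#' @param tail `"neg"` or `"pos"`.
#' @param exactMax exact enumeration when both group sizes are below this
#'   (default 8).
#' @return list: `U`, `p`, `cl_effect` (percent), `n_scz`, `n_ctrl`,
#'   `method`.
#' @export
subjectCountTest <- function(summary, wave, tail = c("neg", "pos"),
                             exactMax = 8) {
  tail <- match.arg(tail)
  sc <- summary@subjectCounts
  sc <- sc[sc$wave == wave, ]
  cnt <- paste0("n_", tail, "_extreme")
  scz <- sc[[cnt]][sc$group == "SCZ"]
  ctl <- sc[[cnt]][sc$group == "CTRL"]
  n1 <- length(scz); n2 <- length(ctl)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  U <- .mw_u(scz, ctl)
  if (n1 <= exactMax && n2 <= exactMax) {
    pool <- c(scz, ctl)
    idx <- combn(n1 + n2, n1)
    Us <- apply(idx, 2, function(i) .mw_u(pool[i], pool[-i]))
    mu <- n1 * n2 / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    ties <- table(c(scz, ctl))
    s2 <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    p <- 2 * pnorm(-abs(U - mu) / sqrt(s2))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p = min(p, 1), cl_effect = 100 * U / (n1 * n2),
       n_scz = n1, n_ctrl = n2, method = method)
}

#' Case-control effect sizes on deviation scores
#'
#' Pooled-SD Cohen's d (SCZ minus CTRL) at one wave, either of the
#' per-subject median z across ROIs (`statistic = "median_roi"`, one
#' number) or per ROI (`"per_roi"`).
#'
#' @param x a scored [CohortExperiment-class].
#' @param wave wave index.
#' @param statistic `"median_roi"` or `"per_roi"`.
#' @param rois optional ROI subset for the median.
#' @return For `"median_roi"` a single-row data.frame (`d`, `n_scz`,
#'   `n_ctrl`); for `"per_roi"` one row per ROI.
#' @export
groupEffectSizes <- function(x, wave, statistic = c("median_roi", "per_roi"),
                             rois = NULL) {
  statistic <- match.arg(statistic)
  cd <- scanData(x)
  sel <- cd$wave == wave
  z <- deviations(x)[, sel, drop = FALSE]
  if (!is.null(rois)) z <- z[rois, , drop = FALSE]
  grp <- cd$group[sel]
  if (sum(grp == "SCZ") < 2 || sum(grp == "CTRL") < 2)
    stop("both groups need at least 2 subjects at wave ", wave)
  cohend <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
    if (sp == 0) return(NA_real_)
    (mean(a) - mean(b)) / sp
  }
  if (statistic == "median_roi") {
    m <- apply(z, 2, median, na.rm = TRUE)
    d <- cohend(m[grp == "SCZ"], m[grp == "CTRL"])
    if (is.na(d)) warning("zero pooled SD: effect size undefined")
    data.frame(statistic = "median_roi", d = d,
               n_scz = sum(grp == "SCZ"), n_ctrl = sum(grp == "CTRL"))
  } else {
    d <- apply(z, 1, function(v) cohend(v[grp == "SCZ"], v[grp == "CTRL"]))
    data.frame(roi = rownames(z), d = d,
               n_scz = sum(grp == "SCZ"), n_ctrl = sum(grp == "CTRL"),
               row.names = NULL)
  }
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up BH procedure at level `alpha`. Missing p-values are excluded
#' from the family but keep their positions in the outputs.
#'
#' @param p numeric p-values in \[0, 1\] (NA allowed).
#' @param alpha FDR level, default 0.05.
#' @return list: `reject` (logical), `q` (BH-adjusted q-values), `alpha`.
#' @export
bhFDR <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), alpha > 0, alpha < 1)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  list(reject = !is.na(q) & q <= alpha, q = q, alpha = alpha)
}
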