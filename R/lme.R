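## Longitudinal linear mixed-effects analyses. All models share the form
##   response ~ fixed terms + (1 | subject), Gaussian, REML by default,
## with Wald t inference on residual df (n_obs - n_fixed) and the signed
## effect size d = sign(beta) * 2|t| / sqrt(residual df).

.code_fixed <- function(d) {
  d$sex_f <- as.numeric(d$sex == "F")
  if (!is.null(d$group)) d$dx <- as.numeric(d$group == "SCZ")
  d
}

#' Fit one linear mixed-effects model
#'
#' Gaussian LME with a subject random intercept, fitted with
#' [lme4::lmer()] (REML by default). Rows with missing response or
#' covariates are dropped and counted. Singular fits (subject variance at
#' zero) fall back to OLS with a flag; inference is Wald t on residual
#' degrees of freedom in both cases. Sex is coded F=1/M=0 and diagnosis
#' SCZ=1/CTRL=0.
#'
#' @param data data.frame with columns `subject_id`, the response, and the
#'   fixed-effect terms.
#' @param response response column name.
#' @param fixed character vector of fixed-effect column names.
#' @param interaction optional length-2 character vector naming two fixed
#'   terms whose product enters the model.
#' @param reml logical, REML (default) or ML.
#' @return list of class `"ctnormLME"`: `coef` (term, beta, se, stat, p,
#'   effect_size), `varcomp`, `n_obs`, `n_subjects`, `converged`,
#'   `singular`, `vcov`, `data_means`.
#' @export
fitLME <- function(data, response, fixed, interaction = NULL, reml = TRUE) {
  data <- .code_fixed(as.data.frame(data))
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2, all(interaction %in% fixed))
    iname <- paste(interaction, collapse = ":")
    data[[paste(interaction, collapse = "_x_")]] <-
      data[[interaction[1]]] * data[[interaction[2]]]
    terms <- c(fixed, paste(interaction, collapse = "_x_"))
  } else {
    iname <- NULL
    terms <- fixed
  }
  use <- complete.cases(data[, c(response, terms, "subject_id")])
  n_dropped <- sum(!use)
  d <- data[use, ]
  fml <- stats::as.formula(paste(
    response, "~", paste(terms, collapse = " + "), "+ (1 | subject_id)"))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(fml, data = d, REML = reml,
      control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) e)
  singular <- FALSE; converged <- TRUE
  if (inherits(fit, "error") ||
      (is.logical(sing <- lme4::isSingular(fit, tol = 1e-5)) && sing)) {
    singular <- TRUE
    ofml <- stats::as.formula(paste(response, "~",
                                    paste(terms, collapse = " + ")))
    ofit <- lm(ofml, data = d)
    beta <- coef(ofit); V <- vcov(ofit)
    vc <- c(subject = 0, residual = summary(ofit)$sigma^2)
    converged <- !inherits(fit, "error")
  } else {
    beta <- lme4::fixef(fit); V <- as.matrix(vcov(fit))
    vcs <- lme4::VarCorr(fit)
    vc <- c(subject = as.numeric(vcs$subject_id),
            residual = attr(vcs, "sc")^2)
    converged <- length(fit@optinfo$conv$lme4) == 0
  }
  se <- sqrt(diag(V))
  n_obs <- nrow(d)
  df <- n_obs - length(beta)
  stat <- beta / se
  cf <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    stat = unname(stat), p = unname(2 * pt(-abs(stat), df)),
    effect_size = unname(sign(beta) * 2 * abs(stat) / sqrt(df)),
    row.names = NULL)
  if (!is.null(iname))
    cf$term <- sub(paste(interaction, collapse = "_x_"), iname, cf$term,
                   fixed = TRUE)
  structure(list(
    coef = cf, varcomp = vc, n_obs = n_obs,
    n_subjects = length(unique(d$subject_id)), n_dropped = n_dropped,
    df = df, converged = converged, singular = singular, vcov = V,
    data_means = vapply(d[, terms, drop = FALSE],
                        function(v) mean(as.numeric(v)), numeric(1)),
    terms = terms, response = response),
    class = "ctnormLME")
}

#' @export
print.ctnormLME <- function(x, ...) {
  cat("Linear mixed model:", x$response, "~",
      paste(x$terms, collapse = " + "), "+ (1 | subject)\n")
  cat("  n_obs:", x$n_obs, " subjects:", x$n_subjects,
      " var(subject):", signif(x$varcomp["subject"], 4),
      " var(resid):", signif(x$varcomp["residual"], 4), "\n")
  if (x$singular) cat("  [singular fit: OLS fallback]\n")
  print(x$coef, digits = 4)
  invisible(x)
}

## long data for the deviation models: one row per scan with covariates
.lme_long <- function(x, rois) {
  cd <- scanData(x)
  z <- deviations(x)
  base <- data.frame(subject_id = cd$subject_id, wave = cd$wave,
                     delay = cd$delay, age_baseline = cd$age_baseline,
                     sex = cd$sex, group = cd$group,
                     panss_total = cd$panss_total,
                     panss_positive = cd$panss_positive,
                     panss_negative = cd$panss_negative,
                     panss_general = cd$panss_general,
                     stringsAsFactors = FALSE)
  list(base = base, z = z[rois, , drop = FALSE])
}

#' Diagnosis-by-time model per ROI
#'
#' Fits, for each ROI, the deviation score on time since inclusion, age at
#' baseline, sex, diagnosis and the diagnosis-by-time interaction, with a
#' subject random intercept. P-values are BH-adjusted across ROIs
#' separately within each fixed-effect term; non-converged ROIs are
#' flagged and excluded from the FDR family.
#'
#' @param x a scored [CohortExperiment-class].
#' @param rois ROI subset (default all scored ROIs).
#' @param alpha FDR level.
#' @param reml logical.
#' @return tidy data.frame: `roi`, `term`, `beta`, `se`, `stat`, `p`, `q`,
#'   `effect_size`, `significant`, `converged`, `singular`, `n`.
#' @export
roiDeviationLME <- function(x, rois = roiNames(x), alpha = 0.05,
                            reml = TRUE) {
  dat <- .lme_long(x, rois)
  res <- lapply(rois, function(roi) {
    d <- dat$base
    d$z <- dat$z[roi, ]
    fit <- fitLME(d, "z", c("delay", "age_baseline", "sex_f", "dx"),
                  interaction = c("delay", "dx"), reml = reml)
    cf <- fit$coef
    cf$roi <- roi
    cf$converged <- fit$converged
    cf$singular <- fit$singular
    cf$n <- fit$n_obs
    cf
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_; out$significant <- FALSE
  for (term in unique(out$term)) {
    i <- which(out$term == term & out$converged)
    fdr <- bhFDR(out$p[i], alpha)
    out$q[i] <- fdr$q
    out$significant[i] <- fdr$reject
  }
  out[, c("roi", "term", "beta", "se", "stat", "p", "q", "effect_size",
          "significant", "converged", "singular", "n")]
}

#' Predicted-value grid for an interaction model
#'
#' Fixed-effects-only predictions over a grid of time-since-inclusion
#' values and diagnosis levels, with the remaining covariates held at
#' their sample means (sex balanced at the sample mean of the F indicator)
#' and delta-method standard errors.
#'
#' @param fit a `"ctnormLME"` from [fitLME()] with a `delay:dx`
#'   interaction.
#' @param delayValues numeric grid of delays (years).
#' @param dxLevels diagnosis levels, default `c(0, 1)`.
#' @return data.frame: `delay`, `dx`, `predicted`, `se`.
#' @export
predictedGrid <- function(fit, delayValues, dxLevels = c(0, 1)) {
  if (!fit$converged) stop("predictedGrid needs a converged fit")
  terms <- fit$terms
  grid <- expand.grid(delay = delayValues, dx = dxLevels)
  Xg <- vapply(terms, function(tm) {
    if (tm == "delay") grid$delay
    else if (tm == "dx") grid$dx
    else if (tm == "delay_x_dx") grid$delay * grid$dx
    else rep(fit$data_means[[tm]], nrow(grid))
  }, numeric(nrow(grid)))
  Xg <- cbind(1, Xg)
  beta <- fit$coef$beta
  grid$predicted <- as.vector(Xg %*% beta)
  grid$se <- sqrt(rowSums((Xg %*% fit$vcov) * Xg))
  grid
}

#' PANSS trajectories over time
#'
#' For each PANSS domain (patients only): a mixed model of the score on
#' time since inclusion, age at baseline and sex with a subject random
#' intercept; plus pairwise wave contrasts from a companion model with
#' wave as a categorical factor, accompanied by unpaired pooled-SD
#' Cohen's d between the per-wave samples (attrition breaks pairing).
#'
#' @param x a [CohortExperiment-class] with PANSS columns.
#' @param domains PANSS domains, default all four.
#' @param reml logical.
#' @return list with `fits` (per-domain `"ctnormLME"`), `coef` (tidy
#'   fixed-effect table) and `contrasts` (per domain and wave pair:
#'   estimate, se, p, cohens_d).
#' @export
panssTimeLME <- function(x, domains = c("total", "positive", "negative",
                                        "general"), reml = TRUE) {
  cd <- scanData(x)
  scz <- cd[cd$group == "SCZ", ]
  if (!nrow(scz)) stop("no patient rows")
  fits <- list(); coefs <- list(); contrasts <- list()
  for (dom in domains) {
    col <- paste0("panss_", dom)
    if (all(is.na(scz[[col]]))) {
      warning("PANSS domain ", dom, " fully missing; skipped")
      next
    }
    d <- data.frame(subject_id = scz$subject_id, y = scz[[col]],
                    delay = scz$delay, age_baseline = scz$age_baseline,
                    sex = scz$sex, wave = scz$wave,
                    stringsAsFactors = FALSE)
    fit <- fitLME(d, "y", c("delay", "age_baseline", "sex_f"), reml = reml)
    fits[[dom]] <- fit
    cf <- fit$coef; cf$domain <- dom
    coefs[[dom]] <- cf
    ## categorical-wave companion model for pairwise contrasts
    d$wave_f <- factor(d$wave)
    wf <- fitLME(cbind(d, .wave_dummies(d$wave_f)), "y",
                 c(colnames(.wave_dummies(d$wave_f)), "age_baseline",
                   "sex_f"), reml = reml)
    waves <- sort(unique(d$wave))
    for (i in seq_along(waves)) for (j in seq_along(waves)) {
      if (j <= i) next
      est_se <- .wave_contrast(wf, waves[i], waves[j])
      a <- d$y[d$wave == waves[j]]; b <- d$y[d$wave == waves[i]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
      contrasts[[paste(dom, waves[i], waves[j])]] <- data.frame(
        domain = dom, wave_from = waves[i], wave_to = waves[j],
        estimate = est_se[1], se = est_se[2],
        p = 2 * pt(-abs(est_se[1] / est_se[2]), wf$df),
        cohens_d = (mean(a) - mean(b)) / sp)
    }
  }
  list(fits = fits, coef = do.call(rbind, coefs),
       contrasts = do.call(rbind, c(contrasts, make.row.names = FALSE)))
}

.wave_dummies <- function(wf) {
  lv <- levels(wf)[-1]
  m <- vapply(lv, function(l) as.numeric(wf == l), numeric(length(wf)))
  colnames(m) <- paste0("wave_", lv)
  as.data.frame(m)
}

.wave_contrast <- function(wf, w_from, w_to) {
  cf <- wf$coef
  nm_to <- paste0("wave_", w_to); nm_from <- paste0("wave_", w_from)
  g <- setNames(numeric(nrow(cf)), cf$term)
  if (nm_to %in% cf$term) g[nm_to] <- 1
  if (nm_from %in% cf$term) g[nm_from] <- -1
  est <- sum(g * cf$beta)
  se <- sqrt(as.numeric(t(g) %*% wf$vcov %*% g))
  c(est, se)
}

#' Symptom-deviation association per ROI
#'
#' For each (ROI, domain) pair in patients: a mixed model of the PANSS
#' score on time since inclusion, age at baseline, sex, the ROI deviation
#' score and the deviation-by-time interaction, with a subject random
#' intercept. BH adjustment across ROIs within each domain, separately for
#' the deviation main effect and the interaction.
#'
#' @param x a scored [CohortExperiment-class] with PANSS columns.
#' @param rois ROI subset.
#' @param domains PANSS domains.
#' @param alpha FDR level.
#' @param reml logical.
#' @return tidy data.frame: `roi`, `domain`, `term`, `beta`, `se`, `stat`,
#'   `p`, `q`, `effect_size`, `significant`, `converged`, `n`.
#' @export
panssDeviationLME <- function(x, rois = roiNames(x),
                              domains = c("total", "positive", "negative",
                                          "general"),
                              alpha = 0.05, reml = TRUE) {
  cd <- scanData(x)
  sel <- cd$group == "SCZ"
  z <- deviations(x)[rois, sel, drop = FALSE]
  scz <- cd[sel, ]
  out <- list()
  for (dom in domains) {
    col <- paste0("panss_", dom)
    if (all(is.na(scz[[col]]))) next
    for (roi in rois) {
      d <- data.frame(subject_id = scz$subject_id, y = scz[[col]],
                      delay = scz$delay, age_baseline = scz$age_baseline,
                      sex = scz$sex, zdev = z[roi, ],
                      stringsAsFactors = FALSE)
      fit <- fitLME(d, "y", c("delay", "age_baseline", "sex_f", "zdev"),
                    interaction = c("delay", "zdev"), reml = reml)
      cf <- fit$coef
      cf$roi <- roi; cf$domain <- dom
      cf$converged <- fit$converged; cf$n <- fit$n_obs
      out[[paste(dom, roi)]] <- cf
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$q <- NA_real_; out$significant <- FALSE
  for (dom in unique(out$domain)) for (term in c("zdev", "delay:zdev")) {
    i <- which(out$domain == dom & out$term == term & out$converged)
    if (!length(i)) next
    fdr <- bhFDR(out$p[i], alpha)
    out$q[i] <- fdr$q
    out$significant[i] <- fdr$reject
  }
  out[, c("roi", "domain", "term", "beta", "se", "stat", "p", "q",
          "effect_size", "significant", "converged", "n")]
}
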