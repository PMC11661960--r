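## Hierarchical Bayesian normative models, per ROI:
##   a_j ~ N(mu_a + delta_f * female_j, tau_a^2)
##   b_j ~ N(mu_b, tau_b^2)
##   log sigma_j ~ N(mu_logsigma, tau_logsigma^2)
##   y ~ N(a_j + b_j * (age - ageCenter), sigma_j^2),  j = (site, sex) batch.
## Default backend is an empirical-Bayes EM: batch posteriors given the
## hyperparameters are conjugate Gaussian in (a, b) and a 1-D MAP in
## log sigma; hyperparameter updates use the batch posterior moments.

.batch_posterior <- function(X, y, sigma, m0, tau2) {
  ## Gaussian posterior of (a, b) given sigma and prior N(m0, diag(tau2))
  P <- diag(1 / tau2, 2) + crossprod(X) / sigma^2
  C <- solve(P)
  m <- C %*% (m0 / tau2 + crossprod(X, y) / sigma^2)
  list(m = as.vector(m), C = C)
}

.sigma_map <- function(X, y, m, C, mu_ls, tau_ls2, n) {
  ## MAP of log sigma with the expected residual sum of squares
  R <- sum((y - X %*% m)^2) + sum(crossprod(X) * C)
  neg <- function(ls) n * ls + R / (2 * exp(2 * ls)) +
    (ls - mu_ls)^2 / (2 * tau_ls2)
  lo <- 0.5 * log(R / n + 1e-12) - 4
  hi <- 0.5 * log(R / n + 1e-12) + 4
  exp(optimize(neg, c(min(lo, mu_ls - 4), max(hi, mu_ls + 4)))$minimum)
}

.fit_roi_em <- function(y, x, batch, female, mu_floor = 1e-6,
                        tol = 1e-6, max_iter = 2000) {
  ub <- sort(unique(batch))
  J <- length(ub)
  Xl <- lapply(ub, function(j) cbind(1, x[batch == j]))
  yl <- lapply(ub, function(j) y[batch == j])
  fem <- vapply(ub, function(j) female[batch == j][1], numeric(1))
  ## initialise from per-batch OLS (pooled slope fallback for tiny batches)
  ab <- t(vapply(seq_len(J), function(j) {
    if (length(yl[[j]]) >= 3 && sd(Xl[[j]][, 2]) > 0) {
      f <- lm.fit(Xl[[j]], yl[[j]])
      c(f$coefficients, sqrt(max(mean(f$residuals^2), 1e-12)))
    } else c(mean(yl[[j]]), 0, max(sd(yl[[j]]), 1e-6))
  }, numeric(3)))
  a <- ab[, 1]; b <- ab[, 2]; sig <- ab[, 3]
  hyp <- c(mu_a = mean(a), delta_f = 0, tau_a = max(sd(a), 1e-3),
           mu_b = mean(b), tau_b = max(sd(b), 1e-4),
           mu_ls = mean(log(sig)), tau_ls = max(sd(log(sig)), 1e-2))
  if (J == 1) hyp[c("tau_a", "tau_b", "tau_ls")] <- c(1, 1, 1)
  conv <- FALSE
  post <- vector("list", J)
  for (it in seq_len(max_iter)) {
    old <- hyp
    for (j in seq_len(J)) {
      m0 <- c(hyp["mu_a"] + hyp["delta_f"] * fem[j], hyp["mu_b"])
      post[[j]] <- .batch_posterior(Xl[[j]], yl[[j]], sig[j], m0,
                                    c(hyp["tau_a"], hyp["tau_b"])^2)
      sig[j] <- .sigma_map(Xl[[j]], yl[[j]], post[[j]]$m, post[[j]]$C,
                           hyp["mu_ls"], hyp["tau_ls"]^2,
                           length(yl[[j]]))
    }
    ma <- vapply(post, function(p) p$m[1], numeric(1))
    mb <- vapply(post, function(p) p$m[2], numeric(1))
    caa <- vapply(post, function(p) p$C[1, 1], numeric(1))
    cbb <- vapply(post, function(p) p$C[2, 2], numeric(1))
    if (J > 1) {
      ## intercept hyper-mean with a female offset when both sexes present
      if (length(unique(fem)) > 1) {
        cf <- coef(lm(ma ~ fem))
        hyp["mu_a"] <- cf[1]; hyp["delta_f"] <- cf[2]
      } else {
        hyp["mu_a"] <- mean(ma); hyp["delta_f"] <- 0
      }
      fit_a <- hyp["mu_a"] + hyp["delta_f"] * fem
      hyp["tau_a"] <- sqrt(max(mean((ma - fit_a)^2 + caa), mu_floor^2))
      hyp["mu_b"] <- mean(mb)
      hyp["tau_b"] <- sqrt(max(mean((mb - hyp["mu_b"])^2 + cbb), 1e-12))
      hyp["mu_ls"] <- mean(log(sig))
      ## Laplace posterior variance of log sigma (information 2n per batch)
      ## keeps the between-batch noise scale from collapsing
      v_ls <- 1 / (2 * vapply(yl, length, integer(1)) + hyp["tau_ls"]^-2)
      hyp["tau_ls"] <- sqrt(max(mean((log(sig) - hyp["mu_ls"])^2 + v_ls),
                                1e-6))
    } else {
      hyp["mu_a"] <- ma; hyp["mu_b"] <- mb; hyp["mu_ls"] <- log(sig)
    }
    if (max(abs(hyp - old)) < tol) { conv <- TRUE; break }
  }
  list(
    hyper = data.frame(mu_a = hyp[["mu_a"]], tau_a = hyp[["tau_a"]],
                       delta_f = hyp[["delta_f"]], mu_b = hyp[["mu_b"]],
                       tau_b = hyp[["tau_b"]], mu_logsigma = hyp[["mu_ls"]],
                       tau_logsigma = hyp[["tau_ls"]]),
    batches = data.frame(
      site = sub(" [FM]$", "", ub), sex = sub("^.* ", "", ub),
      a = vapply(post, function(p) p$m[1], numeric(1)),
      b = vapply(post, function(p) p$m[2], numeric(1)),
      sigma = sig,
      c_aa = vapply(post, function(p) p$C[1, 1], numeric(1)),
      c_ab = vapply(post, function(p) p$C[1, 2], numeric(1)),
      c_bb = vapply(post, function(p) p$C[2, 2], numeric(1)),
      n = vapply(yl, length, integer(1)),
      stringsAsFactors = FALSE),
    converged = conv)
}

#' Fit reference normative models
#'
#' Fits one hierarchical normative model per ROI on healthy-control
#' reference scans, with age (centred at the training mean) as covariate
#' and fully crossed (site, sex) batches. The default backend is a
#' deterministic empirical-Bayes EM; `backend = "mcmc"` uses JAGS (package
#' \pkg{rjags}) and agrees with EM within a few percent on identifiable
#' data. Batches with fewer than `minBatchN` scans are fully shrunk to the
#' hyperprior mean. ROIs whose EM did not converge are flagged in
#' `fitMeta()$converged` and excluded from downstream FDR families.
#'
#' @param x a [CohortExperiment-class] of CTRL scans.
#' @param rois ROI labels to fit (default all).
#' @param backend `"em"` (default) or `"mcmc"`.
#' @param minBatchN minimum scans per batch (default 10).
#' @param varMode `"predictive"` (default; predictive SD includes the batch
#'   parameter uncertainty) or `"noise"` (noise SD only).
#' @param mcmcIter,mcmcBurn iterations for the MCMC backend.
#' @param seed seed for the MCMC backend (EM is seedless).
#' @return A [NormativeModelSet-class].
#' @export
fitReference <- function(x, rois = roiNames(x), backend = c("em", "mcmc"),
                         minBatchN = 10, varMode = c("predictive", "noise"),
                         mcmcIter = 3000, mcmcBurn = 1000, seed = 1) {
  backend <- match.arg(backend)
  varMode <- match.arg(varMode)
  cd <- scanData(x)
  if (any(cd$group != "CTRL"))
    stop("reference fitting requires CTRL scans only")
  batch <- paste(cd$site_id, cd$sex)
  if (length(unique(batch)) < 2)
    warning("fewer than 2 batches: hyperprior SDs are weakly identified")
  center <- mean(cd$age_at_scan)
  xc <- cd$age_at_scan - center
  female <- as.numeric(cd$sex == "F")
  th <- thickness(x)
  small <- names(which(table(batch) < minBatchN))
  keep <- !(batch %in% small)
  hyper_l <- list(); batch_l <- list(); convs <- logical(0)
  for (roi in rois) {
    y <- th[roi, keep]
    fit <- if (backend == "em")
      .fit_roi_em(y, xc[keep], batch[keep], female[keep])
    else .fit_roi_mcmc(y, xc[keep], batch[keep], female[keep],
                       n_iter = mcmcIter, n_burn = mcmcBurn, seed = seed)
    if (!fit$converged)
      warning("normative fit did not converge for ROI ", roi,
              "; flagged and excluded from FDR families")
    h <- fit$hyper; h$roi <- roi
    bt <- fit$batches; bt$roi <- roi
    if (length(small)) {
      ## batches below the floor inherit the hyperprior mean
      sm <- data.frame(site = sub(" [FM]$", "", small),
                       sex = sub("^.* ", "", small), stringsAsFactors = FALSE)
      sm$a <- h$mu_a + h$delta_f * (sm$sex == "F")
      sm$b <- h$mu_b
      sm$sigma <- exp(h$mu_logsigma)
      sm$c_aa <- h$tau_a^2; sm$c_ab <- 0; sm$c_bb <- h$tau_b^2
      sm$n <- as.integer(table(batch)[small])
      sm$roi <- roi
      bt <- rbind(bt, sm[, colnames(bt)])
    }
    hyper_l[[roi]] <- h; batch_l[[roi]] <- bt
    convs[roi] <- fit$converged
  }
  hyper <- do.call(rbind, hyper_l)
  hyper <- hyper[, c("roi", "mu_a", "tau_a", "delta_f", "mu_b", "tau_b",
                     "mu_logsigma", "tau_logsigma")]
  batches <- do.call(rbind, batch_l)
  batches <- batches[, c("roi", "site", "sex", "a", "b", "sigma",
                         "c_aa", "c_ab", "c_bb", "n")]
  rownames(hyper) <- rownames(batches) <- NULL
  methods::new("NormativeModelSet", hyper = hyper, batches = batches,
               ageCenter = center,
               fitMeta = list(backend = backend, n_train = sum(keep),
                              converged = convs, min_batch_n = minBatchN),
               varMode = varMode)
}

#' @describeIn fitReference Hyperparameter table (one row per ROI).
#' @param model a `NormativeModelSet`.
#' @export
hyperParameters <- function(model) model@hyper

#' @describeIn fitReference Batch-level parameter table.
#' @export
batchParameters <- function(model) model@batches

#' @describeIn fitReference Fit metadata (backend, n, convergence flags).
#' @export
fitMeta <- function(model) model@fitMeta

setMethod("show", "NormativeModelSet", function(object) {
  cat("NormativeModelSet:", nrow(object@hyper), "ROIs,",
      length(unique(paste(object@batches$site, object@batches$sex))),
      "batches\n")
  cat("  backend:", object@fitMeta$backend,
      " n_train:", object@fitMeta$n_train,
      " converged:", sum(object@fitMeta$converged), "/",
      length(object@fitMeta$converged), "\n")
  cat("  age centre:", round(object@ageCenter, 2), "years;",
      "variance mode:", object@varMode, "\n")
})

#' Transfer normative models to unseen scanners
#'
#' Re-estimates batch-level parameters for new (site, sex) cells using the
#' frozen reference hyperparameters as informed priors, fitted on held-out
#' local controls. With no adaptation data a new batch sits exactly at the
#' hyperprior mean; with increasing adaptation data it converges to the
#' local OLS estimates (shrinkage). Original batches are untouched.
#'
#' @param model a [NormativeModelSet-class] fitted on the reference.
#' @param adaptation a [CohortExperiment-class] of CTRL scans from the new
#'   sites only.
#' @param newSites character vector of new site ids (must be disjoint from
#'   the model's sites).
#' @return An augmented `NormativeModelSet`.
#' @export
transferModel <- function(model, adaptation, newSites) {
  if (any(newSites %in% model@batches$site))
    stop("newSites overlap the model's existing sites")
  cd <- scanData(adaptation)
  if (any(cd$group != "CTRL"))
    stop("adaptation data must contain held-out controls only")
  if (!all(cd$site_id %in% newSites))
    stop("adaptation rows from sites outside newSites")
  xc <- cd$age_at_scan - model@ageCenter
  add <- list()
  for (roi in model@hyper$roi) {
    h <- model@hyper[model@hyper$roi == roi, ]
    y <- thickness(adaptation)[roi, ]
    for (s in newSites) for (sex in c("F", "M")) {
      sel <- cd$site_id == s & cd$sex == sex
      m0 <- c(h$mu_a + h$delta_f * (sex == "F"), h$mu_b)
      tau2 <- c(h$tau_a, h$tau_b)^2
      if (!any(sel)) {
        row <- data.frame(roi = roi, site = s, sex = sex,
                          a = m0[1], b = m0[2], sigma = exp(h$mu_logsigma),
                          c_aa = tau2[1], c_ab = 0, c_bb = tau2[2], n = 0L)
      } else {
        Xj <- cbind(1, xc[sel]); yj <- y[sel]
        sig <- exp(h$mu_logsigma)
        for (it in 1:100) {
          p <- .batch_posterior(Xj, yj, sig, m0, tau2)
          new_sig <- .sigma_map(Xj, yj, p$m, p$C, h$mu_logsigma,
                                h$tau_logsigma^2, length(yj))
          if (abs(log(new_sig) - log(sig)) < 1e-10) { sig <- new_sig; break }
          sig <- new_sig
        }
        row <- data.frame(roi = roi, site = s, sex = sex,
                          a = p$m[1], b = p$m[2], sigma = sig,
                          c_aa = p$C[1, 1], c_ab = p$C[1, 2],
                          c_bb = p$C[2, 2], n = sum(sel))
      }
      add[[paste(roi, s, sex)]] <- row
    }
  }
  model@batches <- rbind(model@batches, do.call(rbind, add))
  rownames(model@batches) <- NULL
  methods::validObject(model)
  model
}

#' Normative prediction for one batch
#'
#' Predicted thickness and predictive SD at a given age for one (site, sex)
#' cell of one ROI. In `"predictive"` variance mode the SD is
#' `sqrt(sigma^2 + x' C x)` with `C` the batch posterior covariance of
#' (intercept, slope) and `x = (1, age - ageCenter)`; in `"noise"` mode it
#' is the noise SD alone.
#'
#' @param model a [NormativeModelSet-class].
#' @param roi ROI label.
#' @param site,sex batch identifiers.
#' @param age age(s) at scan, years.
#' @return data.frame with `predicted_mean` and `predictive_sd`.
#' @export
predictNormative <- function(model, roi, site, sex, age) {
  b <- model@batches
  row <- b[b$roi == roi & b$site == site & b$sex == sex, ]
  if (!nrow(row))
    stop("unknown batch (", site, ", ", sex, ") for ROI ", roi)
  xc <- age - model@ageCenter
  v <- row$sigma^2
  if (model@varMode == "predictive")
    v <- v + row$c_aa + 2 * xc * row$c_ab + xc^2 * row$c_bb
  data.frame(predicted_mean = row$a + row$b * xc, predictive_sd = sqrt(v))
}

#' Score deviations for a cohort
#'
#' Computes per scan x ROI deviation z-scores against a (possibly
#' transferred) normative model set: `z = (y - predicted_mean) /
#' predictive_sd`, each scan scored with its own scanner's batch
#' parameters. Missing thickness values propagate to missing z and are
#' counted in the completeness report attached to the result's metadata.
#'
#' @param model a [NormativeModelSet-class] covering every (site, sex) in
#'   the cohort.
#' @param x a [CohortExperiment-class].
#' @return `x` with added assays `deviation`, `predicted_mean`,
#'   `predictive_sd`.
#' @export
scoreDeviations <- function(model, x) {
  cd <- scanData(x)
  rois <- intersect(roiNames(x), model@hyper$roi)
  if (!length(rois)) stop("no modelled ROIs present in the cohort")
  need <- unique(paste(cd$site_id, cd$sex))
  have <- unique(paste(model@batches$site, model@batches$sex))
  if (length(setdiff(need, have)))
    stop("batches not covered by the model: ",
         paste(setdiff(need, have), collapse = ", "))
  xs <- x[rois, ]
  th <- thickness(xs)
  xc <- cd$age_at_scan - model@ageCenter
  b <- model@batches
  key_b <- paste(b$roi, b$site, b$sex)
  pm <- ps <- matrix(NA_real_, length(rois), ncol(xs),
                     dimnames = dimnames(th))
  scan_key <- paste(cd$site_id, cd$sex)
  for (k in unique(scan_key)) {
    cols <- which(scan_key == k)
    rows_b <- b[key_b %in% paste(rois, k), ]
    rows_b <- rows_b[match(rois, rows_b$roi), ]
    pm[, cols] <- rows_b$a + outer(rows_b$b, xc[cols])
    v <- rows_b$sigma^2
    if (model@varMode == "predictive") {
      v <- v + rows_b$c_aa +
        2 * outer(rows_b$c_ab, xc[cols]) +
        outer(rows_b$c_bb, xc[cols]^2)
    }
    ps[, cols] <- sqrt(v)
  }
  z <- (th - pm) / ps
  SummarizedExperiment::assay(xs, "deviation") <- z
  SummarizedExperiment::assay(xs, "predicted_mean") <- pm
  SummarizedExperiment::assay(xs, "predictive_sd") <- ps
  S4Vectors::metadata(xs)$completeness <-
    list(n_missing = sum(is.na(z)), n_total = length(z))
  xs
}

#' Calibration report for control deviations
#'
#' Per-ROI mean, SD, skewness and excess kurtosis of control z-scores, with
#' a pass/fail flag at configurable tolerances. On held-out controls from a
#' well-specified (transferred) model, z should be close to standard normal
#' in every ROI, which is what makes deviation scores comparable across
#' scanners.
#'
#' @param x a scored [CohortExperiment-class].
#' @param controlsMask logical per scan; default all CTRL scans.
#' @param meanTol,sdRange tolerances for the pass flag.
#' @return data.frame with one row per ROI.
#' @export
calibrationReport <- function(x, controlsMask = NULL,
                              meanTol = 0.15, sdRange = c(0.85, 1.15)) {
  if (is.null(controlsMask)) controlsMask <- scanData(x)$group == "CTRL"
  z <- deviations(x)[, controlsMask, drop = FALSE]
  if (ncol(z) < 30) stop("calibration needs at least 30 control scans")
  st <- t(apply(z, 1, function(v) {
    v <- v[!is.na(v)]
    m <- mean(v); s <- sd(v)
    c(mean = m, sd = s,
      skew = mean((v - m)^3) / s^3,
      kurtosis = mean((v - m)^4) / s^4 - 3)
  }))
  out <- data.frame(roi = rownames(z), st, row.names = NULL)
  out$pass <- abs(out$mean) <= meanTol &
    out$sd >= sdRange[1] & out$sd <= sdRange[2]
  out
}

#' Serialize normative models to plain text
#'
#' Writes/reads the full model set (hyperparameters, batch parameters, age
#' centre, fit metadata) as a single JSON file.
#'
#' @param model a [NormativeModelSet-class].
#' @param path file path.
#' @return `readNormativeModels()` returns the model set.
#' @export
writeNormativeModels <- function(model, path) {
  obj <- list(hyper = model@hyper, batches = model@batches,
              age_center = model@ageCenter, var_mode = model@varMode,
              fit_meta = model@fitMeta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeNormativeModels
#' @export
readNormativeModels <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fm <- obj$fit_meta
  fm$converged <- setNames(as.logical(fm$converged),
                           names(fm$converged))
  methods::new("NormativeModelSet",
               hyper = as.data.frame(obj$hyper),
               batches = as.data.frame(obj$batches),
               ageCenter = obj$age_center, varMode = obj$var_mode,
               fitMeta = fm)
}

## MCMC backend (JAGS): same model, full posterior over hyperparameters.
.fit_roi_mcmc <- function(y, x, batch, female, n_iter = 3000,
                          n_burn = 1000, seed = 1) {
  if (!requireNamespace("rjags", quietly = TRUE))
    stop("backend 'mcmc' requires the rjags package")
  ub <- sort(unique(batch))
  j <- match(batch, ub)
  fem <- vapply(ub, function(b) female[batch == b][1], numeric(1))
  model_str <- "
    model {
      for (i in 1:N) {
        y[i] ~ dnorm(a[j[i]] + b[j[i]] * x[i], pow(sig[j[i]], -2))
      }
      for (k in 1:J) {
        a[k] ~ dnorm(mu_a + delta_f * fem[k], pow(tau_a, -2))
        b[k] ~ dnorm(mu_b, pow(tau_b, -2))
        ls[k] ~ dnorm(mu_ls, pow(tau_ls, -2))
        sig[k] <- exp(ls[k])
      }
      mu_a ~ dnorm(0, 1e-4); delta_f ~ dnorm(0, 1e-2)
      mu_b ~ dnorm(0, 1); mu_ls ~ dnorm(0, 1e-2)
      tau_a ~ dunif(1e-4, 5); tau_b ~ dunif(1e-6, 1); tau_ls ~ dunif(1e-3, 3)
    }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = y, x = x, j = j, fem = fem, N = length(y), J = length(ub)),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seed),
    n.chains = 1, quiet = TRUE)
  update(jm, n_burn, progress.bar = "none")
  sm <- rjags::coda.samples(
    jm, c("a", "b", "sig", "mu_a", "delta_f", "mu_b", "mu_ls",
          "tau_a", "tau_b", "tau_ls"),
    n.iter = n_iter, progress.bar = "none")[[1]]
  pm <- colMeans(sm)
  g <- function(nm) unname(pm[nm])
  av <- g(paste0("a[", seq_along(ub), "]"))
  bv <- g(paste0("b[", seq_along(ub), "]"))
  sv <- g(paste0("sig[", seq_along(ub), "]"))
  Cab <- lapply(seq_along(ub), function(k)
    stats::cov(sm[, c(paste0("a[", k, "]"), paste0("b[", k, "]"))]))
  list(
    hyper = data.frame(mu_a = g("mu_a"), tau_a = g("tau_a"),
                       delta_f = g("delta_f"), mu_b = g("mu_b"),
                       tau_b = g("tau_b"), mu_logsigma = g("mu_ls"),
                       tau_logsigma = g("tau_ls")),
    batches = data.frame(
      site = sub(" [FM]$", "", ub), sex = sub("^.* ", "", ub),
      a = av, b = bv, sigma = sv,
      c_aa = vapply(Cab, function(C) C[1, 1], numeric(1)),
      c_ab = vapply(Cab, function(C) C[1, 2], numeric(1)),
      c_bb = vapply(Cab, function(C) C[2, 2], numeric(1)),
      n = as.integer(table(batch)[ub]), stringsAsFactors = FALSE),
    converged = TRUE)
}
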