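# Longitudinal mixed models: coefficient recovery, GLS equivalence,
# prediction grids, and the symptom models.

simPanel <- function(n_subj = 60, waves = c(0, 1, 10), beta = c(
                       intercept = 0, delay = 0.05, age_baseline = 0.01,
                       sex_f = -0.1, dx = -0.5, inter = 0.04),
                     sd_u = 0.3, sd_e = 0.5, seed = 1) {
  set.seed(seed)
  subj <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n_subj)),
    age_baseline = runif(n_subj, 20, 50),
    sex = sample(c("F", "M"), n_subj, TRUE),
    group = rep(c("CTRL", "SCZ"), length.out = n_subj),
    u = rnorm(n_subj, 0, sd_u))
  d <- do.call(rbind, lapply(waves, function(w) {
    x <- subj; x$delay <- w; x
  }))
  d$dx_n <- as.numeric(d$group == "SCZ")
  d$z <- beta["intercept"] + beta["delay"] * d$delay +
    beta["age_baseline"] * d$age_baseline +
    beta["sex_f"] * (d$sex == "F") + beta["dx"] * d$dx_n +
    beta["inter"] * d$delay * d$dx_n + d$u + rnorm(nrow(d), 0, sd_e)
  d
}

test_that("near-noiseless data recovers the coefficients", {
  d <- simPanel(40, sd_u = 0, sd_e = 1e-6, seed = 2)
  f <- fitLME(d, "z", c("delay", "age_baseline", "sex_f", "dx"),
              interaction = c("delay", "dx"))
  got <- setNames(f$coef$beta, f$coef$term)
  expect_lt(abs(got[["delay"]] - 0.05), 1e-3)
  expect_lt(abs(got[["dx"]] - (-0.5)), 1e-3)
  expect_lt(abs(got[["delay:dx"]] - 0.04), 1e-3)
  expect_lt(abs(got[["sex_f"]] - (-0.1)), 1e-3)
})

test_that("fixed effects equal the GLS closed form on balanced panels", {
  d <- simPanel(50, waves = c(0, 1), seed = 3)
  f <- fitLME(d, "z", c("delay", "age_baseline", "sex_f", "dx"),
              interaction = c("delay", "dx"))
  ## GLS with the REML-estimated compound-symmetric covariance
  X <- model.matrix(~ delay + age_baseline + I(sex == "F") + dx_n +
                      delay:dx_n, data = d)
  V_inv_blocks <- {
    s2u <- f$varcomp["subject"]; s2e <- f$varcomp["residual"]
    Vb <- matrix(s2u, 2, 2) + diag(s2e, 2)
    solve(Vb)
  }
  ids <- unique(d$subject_id)
  XtVX <- matrix(0, ncol(X), ncol(X)); XtVy <- numeric(ncol(X))
  for (id in ids) {
    i <- which(d$subject_id == id)
    XtVX <- XtVX + t(X[i, ]) %*% V_inv_blocks %*% X[i, ]
    XtVy <- XtVy + t(X[i, ]) %*% V_inv_blocks %*% d$z[i]
  }
  beta_gls <- solve(XtVX, XtVy)
  expect_equal(unname(f$coef$beta), unname(as.vector(beta_gls)),
               tolerance = 1e-6)
})

test_that("estimates are invariant to subject relabeling and row order", {
  d <- simPanel(40, seed = 4)
  f1 <- fitLME(d, "z", c("delay", "dx"), interaction = c("delay", "dx"))
  d2 <- d[sample(nrow(d)), ]
  d2$subject_id <- factor(d2$subject_id,
                          levels = sample(unique(d2$subject_id)))
  f2 <- fitLME(d2, "z", c("delay", "dx"), interaction = c("delay", "dx"))
  expect_equal(f1$coef$beta, f2$coef$beta, tolerance = 1e-8)
})

test_that("ML and REML agree on large balanced panels", {
  d <- simPanel(400, seed = 5)
  f1 <- fitLME(d, "z", c("delay", "dx"), interaction = c("delay", "dx"))
  f2 <- fitLME(d, "z", c("delay", "dx"), interaction = c("delay", "dx"),
               reml = FALSE)
  rel <- abs(f1$coef$beta - f2$coef$beta) /
    pmax(abs(f1$coef$beta), 0.01)
  expect_true(all(rel < 0.01))
  expect_true(all(f1$varcomp >= 0))
})

test_that("singular fits fall back to OLS with a flag", {
  d <- simPanel(40, sd_u = 0, sd_e = 0.5, seed = 6)
  f <- fitLME(d, "z", c("delay", "dx"), interaction = c("delay", "dx"))
  if (f$singular) {
    ols <- lm(z ~ delay + dx_n + delay:dx_n, data = d)
    expect_equal(unname(f$coef$beta), unname(coef(ols)), tolerance = 1e-8)
  }
  expect_true(is.logical(f$singular))
})

test_that("per-ROI diagnosis model flags the affected regions", {
  fx <- scoredFixture()
  res <- roiDeviationLME(fx$scored)
  expect_setequal(unique(res$term),
                  c("(Intercept)", "delay", "age_baseline", "sex_f", "dx",
                    "delay:dx"))
  dx <- res[res$term == "dx", ]
  affected <- rownames(fx$scored)[1:3]
  ## conditional main effect of diagnosis is negative on affected ROIs
  expect_true(all(dx$beta[dx$roi %in% affected] < 0))
  ## interaction runs against the main effect (attenuation)
  int <- res[res$term == "delay:dx", ]
  expect_true(mean(int$beta[int$roi %in% affected] > 0) >= 2 / 3)
})

test_that("permuting diagnosis within wave destroys the dx effect", {
  fx <- scoredFixture()
  sc <- fx$scored
  cd <- scanData(sc)
  set.seed(9)
  ## permute subject-level labels, then rebuild scan-level labels
  subj <- unique(cd[, c("subject_id", "group")])
  subj$group_perm <- sample(subj$group)
  cd$group <- subj$group_perm[match(cd$subject_id, subj$subject_id)]
  cd$panss_total[cd$group == "CTRL"] <- NA
  cd$panss_positive[cd$group == "CTRL"] <- NA
  cd$panss_negative[cd$group == "CTRL"] <- NA
  cd$panss_general[cd$group == "CTRL"] <- NA
  SummarizedExperiment::colData(sc) <-
    S4Vectors::DataFrame(cd, row.names = colnames(sc))
  res <- roiDeviationLME(sc)
  expect_equal(sum(res$significant[res$term == "dx"]), 0)
})

test_that("prediction grids reflect the fitted interaction", {
  d <- simPanel(120, seed = 7)
  f <- fitLME(d, "z", c("delay", "age_baseline", "sex_f", "dx"),
              interaction = c("delay", "dx"))
  g <- predictedGrid(f, delayValues = c(0, 1, 5, 10))
  ## matches direct evaluation at the covariate means
  bt <- setNames(f$coef$beta, f$coef$term)
  mean_age <- f$data_means[["age_baseline"]]
  mean_sex <- f$data_means[["sex_f"]]
  manual <- bt[["(Intercept)"]] + bt[["delay"]] * g$delay +
    bt[["age_baseline"]] * mean_age + bt[["sex_f"]] * mean_sex +
    bt[["dx"]] * g$dx + bt[["delay:dx"]] * g$delay * g$dx
  expect_equal(g$predicted, unname(manual), tolerance = 1e-10)
  ## group curves cross where delay = -beta_dx / beta_interaction
  cross <- -bt[["dx"]] / bt[["delay:dx"]]
  gc <- predictedGrid(f, delayValues = cross)
  expect_equal(gc$predicted[1], gc$predicted[2], tolerance = 1e-8)
  ## without an interaction the curves are parallel
  d0 <- simPanel(120, beta = c(intercept = 0, delay = 0.05,
                               age_baseline = 0.01, sex_f = -0.1,
                               dx = -0.5, inter = 0), seed = 8)
  f0 <- fitLME(d0, "z", c("delay", "age_baseline", "sex_f", "dx"),
               interaction = c("delay", "dx"))
  b0 <- setNames(f0$coef$beta, f0$coef$term)
  g0 <- predictedGrid(f0, delayValues = c(0, 10))
  gap <- function(w) diff(g0$predicted[g0$delay == w])
  expect_equal(gap(0) - gap(10), -10 * b0[["delay:dx"]],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("symptom trajectories recover the simulated time slope", {
  cfg <- smallConfig(nPatientsClin = 120, nControlsClin = 20,
                     attritionRate = 0.1)
  clin <- suppressMessages(generateClinical(cfg))
  fx <- scoredFixture()
  sc <- scoreDeviations(fx$model, clin)
  res <- panssTimeLME(sc)
  slope <- res$coef[res$coef$domain == "total" &
                    res$coef$term == "delay", ]
  expect_lt(abs(slope$beta - (-1.4)), 2 * slope$se)
  expect_lt(slope$p, 0.05)
  ## wave contrasts: symptoms drop from baseline to the last wave
  ct <- res$contrasts
  last <- ct[ct$domain == "total" & ct$wave_from == 0 & ct$wave_to == 2, ]
  expect_lt(last$estimate, 0)
  expect_lt(last$cohens_d, 0)
})

test_that("wave-contrast effect size tracks a simulated shift", {
  set.seed(10)
  ds <- vapply(1:10, function(i) {
    n <- 150
    y0 <- rnorm(n, 60, 10); y1 <- rnorm(n, 55, 10)  # -0.5 SD shift
    sp <- sqrt((var(y0) + var(y1)) / 2)
    (mean(y1) - mean(y0)) / sp
  }, numeric(1))
  expect_lt(abs(mean(ds) - (-0.5)), 0.15)
  ## the packaged contrast uses the same pooled-SD definition
  cfg <- smallConfig(nPatientsClin = 100, nControlsClin = 20)
  clin <- suppressMessages(generateClinical(cfg))
  fx <- scoredFixture()
  res <- panssTimeLME(scoreDeviations(fx$model, clin))
  ct <- res$contrasts[res$contrasts$domain == "total" &
                      res$contrasts$wave_from == 0 &
                      res$contrasts$wave_to == 1, ]
  cd <- scanData(clin)
  y0 <- cd$panss_total[cd$group == "SCZ" & cd$wave == 0]
  y1 <- cd$panss_total[cd$group == "SCZ" & cd$wave == 1]
  sp <- sqrt(((length(y0) - 1) * var(y0) + (length(y1) - 1) * var(y1)) /
             (length(y0) + length(y1) - 2))
  expect_equal(ct$cohens_d, (mean(y1) - mean(y0)) / sp, tolerance = 1e-10)
})

test_that("deviation-symptom coupling is recovered and nulls stay clean", {
  cfg <- smallConfig(nPatientsClin = 150, nControlsClin = 20,
                     panssCoupling = list(total = c("2" = -3)),
                     attritionRate = 0.1)
  clin <- suppressMessages(generateClinical(cfg))
  fx <- scoredFixture()
  sc <- scoreDeviations(fx$model, clin)
  res <- panssDeviationLME(sc, domains = "total")
  hit <- res[res$roi == rownames(sc)[2] & res$term == "zdev", ]
  expect_lt(abs(hit$beta - (-3)), 2 * hit$se)
  expect_true(hit$significant)
  others <- res[res$roi != rownames(sc)[2] & res$term == "zdev", ]
  expect_lte(sum(others$significant), 1)
})

test_that("null coupling yields no FDR discoveries", {
  fx <- scoredFixture()  # default config has no PANSS-deviation coupling
  res <- panssDeviationLME(fx$scored, domains = "total")
  expect_lte(sum(res$significant[res$term == "zdev"]), 1)
})
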