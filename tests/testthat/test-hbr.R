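# Hierarchical normative models: EM recovery, transfer shrinkage,
# prediction, scoring, calibration, and backend agreement.

test_that("noiseless data recovers batch parameters almost exactly", {
  cfg <- SyntheticConfig(nSitesRef = 3, subjectsPerSiteRef = 60, nRois = 2,
                         hyperLogNoise = c(mean = log(1e-6), sd = 0),
                         roiLogNoiseSd = 0, subjectOffsetSd = 0, seed = 3)
  ref <- generateReference(cfg)
  m <- fitReference(ref, minBatchN = 5)
  tr <- S4Vectors::metadata(ref)$truth$batches
  b <- batchParameters(m)
  mg <- merge(b, tr, by = c("roi", "site", "sex"),
              suffixes = c("_fit", "_true"))
  ## fitted intercept is at the age centre
  a_true_centered <- mg$a_true + mg$b_true * m@ageCenter
  expect_lt(max(abs(mg$a_fit - a_true_centered)), 1e-3)
  expect_lt(max(abs(mg$b_fit - mg$b_true)), 1e-3)
})

test_that("a single batch reproduces its OLS estimates", {
  set.seed(11)
  n <- 200
  age <- runif(n, 20, 60)
  y <- 2.6 - 0.004 * age + rnorm(n, 0, 0.1)
  ce <- CohortExperiment(
    matrix(y, 1, dimnames = list("lh_G_cuneus", NULL)),
    data.frame(subject_id = sprintf("s%03d", 1:n), site_id = "one",
               group = "CTRL", wave = 0L, delay = 0, age_at_scan = age,
               age_baseline = age, sex = "M", qc_metric = 0L))
  m <- suppressWarnings(fitReference(ce, minBatchN = 5))
  xc <- age - mean(age)
  ols <- coef(lm(y ~ xc))
  b <- batchParameters(m)
  expect_lt(abs(b$a - ols[1]), 1e-6)
  expect_lt(abs(b$b - ols[2]), 1e-6)
})

test_that("hyperparameters are recovered on a multi-site reference", {
  cfg <- SyntheticConfig(nSitesRef = 10, subjectsPerSiteRef = 100, nRois = 3,
                         seed = 19)
  ref <- generateReference(cfg)
  m <- fitReference(ref)
  tr <- S4Vectors::metadata(ref)$truth$roi
  h <- hyperParameters(m)
  J <- 20  # batches
  for (i in seq_len(nrow(h))) {
    a_true <- tr$A[i] + tr$B[i] * m@ageCenter  # centred intercept
    expect_lt(abs(h$mu_a[i] - a_true), 3 * h$tau_a[i] / sqrt(J) + 0.02)
    expect_lt(abs(h$mu_b[i] - tr$B[i]), 3 * h$tau_b[i] / sqrt(J) + 5e-4)
    expect_lt(abs(exp(h$mu_logsigma[i]) - exp(tr$L[i])),
              0.25 * exp(tr$L[i]))
  }
})

test_that("transfer with no adaptation data sits at the hyperprior mean", {
  fx <- scoredFixture()
  m <- fitReference(generateReference(smallConfig()), minBatchN = 10)
  empty <- generateAdaptation(smallConfig(), nPerSite = 2)[, 0]
  m2 <- transferModel(m, empty, "clinX")
  h <- hyperParameters(m2)
  b <- batchParameters(m2)
  new <- b[b$site == "clinX", ]
  for (roi in h$roi) {
    hr <- h[h$roi == roi, ]
    expect_equal(new$a[new$roi == roi & new$sex == "F"],
                 hr$mu_a + hr$delta_f)
    expect_equal(new$a[new$roi == roi & new$sex == "M"], hr$mu_a)
    expect_equal(new$b[new$roi == roi], rep(hr$mu_b, 2))
    expect_equal(new$sigma[new$roi == roi], rep(exp(hr$mu_logsigma), 2))
  }
})

test_that("large adaptation samples recover the new scanner's truth", {
  cfg <- SyntheticConfig(nSitesRef = 8, subjectsPerSiteRef = 80, nRois = 2,
                         seed = 23)
  ref <- generateReference(cfg)
  m <- fitReference(ref)
  adapt <- generateAdaptation(cfg, nPerSite = 4000)
  m2 <- transferModel(m, adapt, unique(scanData(adapt)$site_id))
  tr <- S4Vectors::metadata(adapt)$truth$batches
  b <- batchParameters(m2)
  b <- b[b$site %in% tr$site, ]
  mg <- merge(b, tr, by = c("roi", "site", "sex"),
              suffixes = c("_fit", "_true"))
  a_true_c <- mg$a_true + mg$b_true * m@ageCenter
  expect_lt(max(abs(mg$a_fit - a_true_c) / a_true_c), 0.01)
  expect_lt(max(abs(mg$sigma_fit - mg$sigma_true) / mg$sigma_true), 0.06)
})

test_that("adapted intercepts shrink between prior mean and OLS", {
  ## symmetric ages around the model's age centre make the intercept
  ## posterior a one-dimensional shrinkage, so strict betweenness holds
  cfg0 <- SyntheticConfig(nSitesRef = 6, subjectsPerSiteRef = 60, nRois = 1,
                          seed = 29)
  ref <- generateReference(cfg0)
  m <- fitReference(ref)
  h <- hyperParameters(m)
  roi <- h$roi[1]
  between <- vapply(1:20, function(s) {
    set.seed(900 + s)
    n <- 10
    ages <- m@ageCenter + c(-seq_len(n / 2), seq_len(n / 2)) * 2
    a_true <- h$mu_a + 0.15; b_true <- h$mu_b
    y <- a_true + b_true * (ages - m@ageCenter) + rnorm(n, 0, 0.12)
    ad1 <- CohortExperiment(
      matrix(y, 1, dimnames = list(roi, NULL)),
      data.frame(subject_id = sprintf("a%02d", 1:n), site_id = "clinA",
                 group = "CTRL", wave = 0L, delay = 0, age_at_scan = ages,
                 age_baseline = ages, sex = "M", qc_metric = 0L))
    m2 <- transferModel(m, ad1, "clinA")
    b <- batchParameters(m2)
    fit_a <- b$a[b$site == "clinA" & b$sex == "M"]
    ols_a <- mean(y)  # intercept OLS under the symmetric design
    (fit_a > min(h$mu_a, ols_a)) && (fit_a < max(h$mu_a, ols_a))
  }, logical(1))
  expect_true(all(between))
})

test_that("prediction follows the linear model and its uncertainty", {
  fx <- scoredFixture()
  m <- fx$model
  b <- batchParameters(m)[1, ]
  p0 <- predictNormative(m, b$roi, b$site, b$sex, m@ageCenter)
  expect_equal(p0$predicted_mean, b$a)
  expect_equal(p0$predictive_sd, sqrt(b$sigma^2 + b$c_aa))
  ## predictive variance is a convex quadratic in age: it grows away from
  ## its vertex (the vertex sits near the age centre, offset by the small
  ## intercept-slope posterior covariance)
  ages <- m@ageCenter + seq(-40, 40, by = 5)
  sds <- predictNormative(m, b$roi, b$site, b$sex, ages)$predictive_sd
  expect_true(all(diff(diff(sds^2)) > -1e-12))
  vertex <- m@ageCenter - b$c_ab / b$c_bb
  right <- predictNormative(m, b$roi, b$site, b$sex,
                            vertex + seq(0, 30, 5))$predictive_sd
  left <- predictNormative(m, b$roi, b$site, b$sex,
                           vertex - seq(0, 30, 5))$predictive_sd
  expect_true(all(diff(right) >= -1e-12))
  expect_true(all(diff(left) >= -1e-12))
  expect_error(predictNormative(m, b$roi, "nowhere", "F", 50), "nowhere")
})

test_that("predictive SD matches a Monte-Carlo posterior-predictive draw", {
  fx <- scoredFixture()
  m <- fx$model
  b <- batchParameters(m)[3, ]
  age <- m@ageCenter + 12
  x <- c(1, 12)
  C <- matrix(c(b$c_aa, b$c_ab, b$c_ab, b$c_bb), 2)
  set.seed(1)
  draws <- MASS::mvrnorm(1e5, c(b$a, b$b), C) %*% x +
    rnorm(1e5, 0, b$sigma)
  p <- predictNormative(m, b$roi, b$site, b$sex, age)
  expect_lt(abs(sd(draws) - p$predictive_sd) / p$predictive_sd, 0.02)
})

test_that("deviation scores are exact standardisations", {
  fx <- scoredFixture()
  sc <- fx$scored
  z <- deviations(sc)
  pm <- SummarizedExperiment::assay(sc, "predicted_mean")
  ps <- SummarizedExperiment::assay(sc, "predictive_sd")
  expect_equal(z, (thickness(sc) - pm) / ps)
  expect_true(all(ps > 0))
  ## y at the predicted mean gives z = 0; at mean + 2 sd gives z = 2
  sc2 <- fx$clin
  th <- thickness(sc2)
  th[1, ] <- pm[1, ]
  th[2, ] <- pm[2, ] + 2 * ps[2, ]
  SummarizedExperiment::assay(sc2, "thickness") <- th
  z2 <- deviations(scoreDeviations(fx$model, sc2))
  expect_equal(unname(z2[1, ]), rep(0, ncol(sc2)))
  expect_equal(unname(z2[2, ]), rep(2, ncol(sc2)))
})

test_that("z-scores are invariant to a global rescaling of the data", {
  cfg <- smallConfig()
  ref <- generateReference(cfg)
  clin <- suppressMessages(generateClinical(cfg))
  adapt <- generateAdaptation(cfg, nPerSite = 150)
  score_with_scale <- function(c_) {
    scale_ce <- function(ce) {
      SummarizedExperiment::assay(ce, "thickness") <-
        thickness(ce) * c_
      ce
    }
    m <- fitReference(scale_ce(ref))
    m <- transferModel(m, scale_ce(adapt), unique(scanData(adapt)$site_id))
    deviations(scoreDeviations(m, scale_ce(clin)))
  }
  z1 <- score_with_scale(1)
  z1000 <- score_with_scale(1000)
  expect_lt(max(abs(z1 - z1000)), 1e-4)
})

test_that("held-out controls are calibrated after transfer", {
  fx <- scoredFixture()
  val <- generateAdaptation(fx$cfg, nPerSite = 250, subseed = 55)
  zv <- deviations(scoreDeviations(fx$model, val))
  expect_lt(max(abs(rowMeans(zv))), 0.15)
  expect_true(all(apply(zv, 1, sd) > 0.85 & apply(zv, 1, sd) < 1.15))
})

test_that("control z distributions align across scanners", {
  ## ample adaptation data per scanner, as in the transfer design
  fx <- scoredFixture()
  adapt <- generateAdaptation(fx$cfg, nPerSite = 2000, subseed = 54)
  model <- transferModel(fx$refModel, adapt,
                         unique(scanData(adapt)$site_id))
  val <- generateAdaptation(fx$cfg, nPerSite = 250, subseed = 56)
  zv <- deviations(scoreDeviations(model, val))
  site <- scanData(val)$site_id
  pairs <- combn(unique(site), 2)
  ps <- unlist(lapply(seq_len(ncol(pairs)), function(k)
    apply(zv, 1, function(v)
      suppressWarnings(stats::ks.test(v[site == pairs[1, k]],
                                      v[site == pairs[2, k]])$p.value))))
  expect_gte(mean(ps > 0.01), 0.9)
})

test_that("calibration report flags shifts and wrong-site scoring", {
  set.seed(42)
  n <- 10000; r <- 5
  mk <- function(zmat) {
    ce <- CohortExperiment(
      matrix(2.5, r, n, dimnames = list(destrieuxLabels(r), NULL)),
      data.frame(subject_id = sprintf("s%05d", 1:n), site_id = "x",
                 group = "CTRL", wave = 0L, delay = 0, age_at_scan = 40,
                 age_baseline = 40, sex = "M", qc_metric = 0L))
    SummarizedExperiment::assay(ce, "deviation", withDimnames = FALSE) <-
      zmat
    ce
  }
  z <- matrix(rnorm(r * n), r)
  rep1 <- calibrationReport(mk(z))
  expect_true(all(rep1$pass))
  rep2 <- calibrationReport(mk(z + 0.5))
  expect_false(any(rep2$pass))
  ## scoring with the wrong scanner's parameters detectably mis-calibrates
  fx <- scoredFixture()
  val <- generateAdaptation(fx$cfg, nPerSite = 250, subseed = 57)
  cd <- scanData(val)
  swapped <- val
  cd2 <- cd
  cd2$site_id <- c(clinA = "clinB", clinB = "clinC",
                   clinC = "clinA")[cd$site_id]
  SummarizedExperiment::colData(swapped) <-
    S4Vectors::DataFrame(cd2, row.names = colnames(val))
  zsw <- scoreDeviations(fx$model, swapped)
  repsw <- calibrationReport(zsw)
  expect_false(all(repsw$pass))
})

test_that("serialization round-trips the model set", {
  fx <- scoredFixture()
  p <- tempfile(fileext = ".json")
  writeNormativeModels(fx$model, p)
  m2 <- readNormativeModels(p)
  expect_equal(hyperParameters(m2), hyperParameters(fx$model),
               tolerance = 1e-12)
  expect_equal(batchParameters(m2)$a, batchParameters(fx$model)$a,
               tolerance = 1e-12)
  expect_equal(m2@ageCenter, fx$model@ageCenter)
  z1 <- deviations(scoreDeviations(fx$model, fx$clin))
  z2 <- deviations(scoreDeviations(m2, fx$clin))
  expect_equal(z1, z2, tolerance = 1e-8)
})

test_that("EM and MCMC backends agree on an identifiable fit", {
  skip_if_not_installed("rjags")
  cfg <- SyntheticConfig(nSitesRef = 4, subjectsPerSiteRef = 80, nRois = 1,
                         seed = 37)
  ref <- generateReference(cfg)
  em <- fitReference(ref)
  mc <- fitReference(ref, backend = "mcmc", mcmcIter = 4000,
                     mcmcBurn = 1500, seed = 5)
  be <- batchParameters(em); bm <- batchParameters(mc)
  mg <- merge(be, bm, by = c("roi", "site", "sex"),
              suffixes = c("_em", "_mc"))
  ## compare fitted normative surfaces and noise levels
  for (dx in c(-15, 0, 15)) {
    mu_em <- mg$a_em + mg$b_em * dx
    mu_mc <- mg$a_mc + mg$b_mc * dx
    expect_lt(max(abs(mu_em - mu_mc) / mu_mc), 0.05)
  }
  expect_lt(max(abs(mg$sigma_em - mg$sigma_mc) / mg$sigma_mc), 0.05)
})

test_that("fitting rejects cohorts containing patients", {
  fx <- scoredFixture()
  expect_error(fitReference(fx$clin), "CTRL")
  expect_error(transferModel(fx$model, fx$clin, "clinZ"), "controls")
})
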