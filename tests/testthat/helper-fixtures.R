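# Shared small fixtures, built once per test run. Sizes are kept small so
# the whole suite stays fast; scientific checks at realistic scale live in
# test-acceptance.R.

smallConfig <- function(...) {
  base <- list(nSitesRef = 6, subjectsPerSiteRef = 60, nRois = 6,
               nControlsClin = 80, nPatientsClin = 40,
               affectedRois = 1:3, seed = 7)
  do.call(SyntheticConfig, utils::modifyList(base, list(...)))
}

# one fitted + transferred + scored cohort reused across test files
.fx <- new.env()

scoredFixture <- function() {
  if (!is.null(.fx$scored)) return(.fx)
  cfg <- smallConfig(nSitesRef = 8, subjectsPerSiteRef = 80)
  ref <- generateReference(cfg)
  sp <- splitReference(ref, 0.9, seed = 2)
  model <- fitReference(sp$train)
  clin <- suppressMessages(generateClinical(cfg))
  adapt <- generateAdaptation(cfg, nPerSite = 600)
  .fx$refModel <- model
  model <- transferModel(model, adapt, unique(scanData(adapt)$site_id))
  .fx$cfg <- cfg
  .fx$model <- model
  .fx$clin <- clin
  .fx$scored <- scoreDeviations(model, clin)
  .fx$validation <- sp$validation
  .fx
}
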