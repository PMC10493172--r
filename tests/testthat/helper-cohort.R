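# Shared fixtures, built once per test run. The main cohort is generated at
# the study's default parameters (n = 30); the null cohort switches off the
# severity-to-image coupling so texture is independent of CAC given the
# clinical covariates.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

sharedCohort <- function() {
  memo("cohort30", function()
    generateCohort(cohortParams(n_subjects = 30, seed = 101)))
}

sharedFeatures <- function() {
  memo("features30", function()
    extractFeatureTable(sharedCohort(), gls = 64L))
}

## stacked 166-column matrix at GL 64 (after the catalog stages)
shared166 <- function() {
  memo("mat166", function() {
    s2 <- stage2DropNonquantitative(stage1DropAggregations(buildCatalog()))
    m <- spectRadiomics:::stackedFeatureMatrix(sharedFeatures(), 64L)
    m[, intersect(colnames(m), s2$feature_id), drop = FALSE]
  })
}

sharedNullCohort <- function() {
  memo("nullCohort", function()
    generateCohort(cohortParams(n_subjects = 45, seed = 202,
                                severity_effect = 0)))
}

sharedNullFeatures <- function() {
  memo("nullFeatures", function()
    extractFeatureTable(sharedNullCohort(), gls = 64L))
}

## small fast cohort for structural/io tests: tiny grid, no texture field
fastParams <- function(n = 3, seed = 7, ...) {
  cohortParams(n_subjects = n, seed = seed, grid_shape = c(24L, 24L, 24L),
               voxel_mm = 4.8, wall_thickness_mm = 18,
               outer_radii_mm = c(48, 48, 52),
               texture_rel_sd = 0.15, texture_corr_len_mm = 10, ...)
}

fastCohort <- function() {
  memo("fastCohort", function() generateCohort(fastParams()))
}

## synthetic modeling dataset on plain tables (no images): k noise features
## plus optional planted effects through a feature and the age covariate
tableDataset <- function(n = 60, k = 8, beta_feat = 0, beta_clin = 0,
                         seed = 1, sd_noise = 1) {
  set.seed(seed)
  p <- cohortParams(n_subjects = n)
  cl <- sampleClinical(p, n)
  fm <- matrix(rnorm(n * k), n, k,
               dimnames = list(NULL, paste0("feat", seq_len(k))))
  y <- beta_clin * (cl$age - 62) / 12 + beta_feat * fm[, 1] +
    rnorm(n, sd = sd_noise)
  data <- cbind(cl, as.data.frame(fm))
  list(y = y, data = data, design = buildDesign(data))
}
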