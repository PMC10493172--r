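test_that("clinical sampling recovers the configured marginals", {
  p <- cohortParams(n_subjects = 1)
  set.seed(42)
  cl <- sampleClinical(p, 10000)
  expect_equal(nrow(cl), 10000)
  ## joint check across all seven categoricals: a goodness-of-fit test per
  ## variable at a conservative level keeps the family-wise false-alarm
  ## probability below 1%, unlike stacking per-rate 2-s.e. intervals
  marg <- p$clinical_marginals
  for (nm in names(marg)) {
    obs <- table(cl[[nm]])
    gof <- suppressWarnings(
      chisq.test(as.vector(obs), p = marg[[nm]] / sum(marg[[nm]])))
    expect_gt(gof$p.value, 1e-3)
  }
  ## rates land close to the configured targets in absolute terms
  expect_lt(abs(mean(cl$diabetes == "Yes") - 0.321), 0.02)
  expect_lt(abs(mean(cl$hypertension == "Yes") - 0.701), 0.02)
  expect_true(all(cl$lvef > 0 & cl$lvef < 100))
  expect_true(all(cl$age > 0))
})

test_that("single-record sampling populates every field", {
  set.seed(1)
  cl <- sampleClinical(cohortParams(n_subjects = 1), 1)
  expect_equal(nrow(cl), 1)
  expect_false(anyNA(cl))
  expect_equal(ncol(cl), 10)
})

test_that("malformed marginals are rejected", {
  expect_error(cohortParams(clinical_marginals =
                              list(diabetes = c(No = 0.5, Yes = 0.2))),
               "sum to 1")
  expect_error(cohortParams(n_subjects = 0), "at least 1")
  expect_error(cohortParams(outer_radii_mm = c(10, 42, 72),
                            wall_thickness_mm = 15), "exceed")
})

test_that("the CAC hurdle behaves at its limits", {
  p <- cohortParams(n_subjects = 1)
  set.seed(5)
  cl <- sampleClinical(p, 50)
  sv <- sampleSeverity(p, cl)
  ## hurdle forced off -> all zero, Berman category 1
  p0 <- p; p0$cac_hurdle_coeffs["intercept"] <- -50
  cc <- sampleCac(cl, sv, p0)
  expect_true(all(cc$total == 0))
  expect_true(all(cc$berman_total == 1L))
  ## infinite-severity limit -> every artery positive
  cc1 <- sampleCac(cl, sv + 1e6, p)
  expect_true(all(cc1$lad > 0 & cc1$lcx > 0 & cc1$rca > 0))
  ## totals always decompose
  cc2 <- sampleCac(cl, sv, p)
  expect_equal(cc2$total, cc2$lad + cc2$lcx + cc2$rca)
})

test_that("default hurdle calibration gives ~58.4% non-zero total CAC", {
  p <- cohortParams(n_subjects = 1)
  set.seed(88)
  cl <- sampleClinical(p, 5000)
  sv <- sampleSeverity(p, cl)
  cc <- sampleCac(cl, sv, p)
  se <- sqrt(0.584 * (1 - 0.584) / 5000)
  expect_lt(abs(mean(cc$total > 0) - 0.584), 2 * se)
})

test_that("a zero-severity noiseless render is a constant shell", {
  p <- cohortParams(n_subjects = 1, texture_rel_sd = 0,
                    noise_poisson_scale = 0, artifact_prob = 0)
  set.seed(2)
  s <- renderSubject(p, c(0, 0, 0))
  vals <- s$image[s$masks$MYO]
  expect_equal(vals, rep(p$base_counts, length(vals)))
})

test_that("segment masks partition as designed", {
  set.seed(3)
  s <- renderSubject(cohortParams(n_subjects = 1), c(1, 1, 1))
  m <- s$masks
  ## tight vascular wedges are pairwise disjoint and inside the myocardium
  expect_equal(sum(m$LAD_MIM & m$LCX_MIM), 0)
  expect_equal(sum(m$LAD_MIM & m$RCA_MIM), 0)
  expect_equal(sum(m$LCX_MIM & m$RCA_MIM), 0)
  expect_true(all(m$MYO[m$LAD_MIM]))
  ## the 17-style grouping partitions the whole shell
  u <- m$LAD_17 | m$LCX_17 | m$RCA_17
  expect_equal(u, m$MYO)
  expect_equal(sum(m$LAD_17 & m$LCX_17), 0)
  expect_equal(sum(m$LAD_17 & m$RCA_17), 0)
  expect_equal(sum(m$LCX_17 & m$RCA_17), 0)
})

test_that("the tight LAD wedge averages about 460 voxels", {
  p <- cohortParams(n_subjects = 1, texture_rel_sd = 0,
                    noise_poisson_scale = 0)
  set.seed(19)
  sizes <- replicate(80, sum(renderSubject(p, c(0, 0, 0))$masks$LAD_MIM))
  expect_lt(abs(mean(sizes) - 460) / 460, 0.10)
})

test_that("cohort generation is deterministic given the seed", {
  a <- generateCohort(fastParams(n = 2, seed = 31))
  b <- generateCohort(fastParams(n = 2, seed = 31))
  expect_identical(a@images, b@images)
  expect_identical(as.data.frame(a@cac), as.data.frame(b@cac))
  d1 <- tempfile(); d2 <- tempfile()
  writeCohort(a, d1); writeCohort(b, d2)
  for (f in c("clinical.csv", "cac.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated cohorts have complete per-subject artifacts", {
  ch <- fastCohort()
  expect_equal(length(ch), 3)
  d <- tempfile()
  writeCohort(ch, d)
  expect_equal(length(list.files(file.path(d, "images"))), 3)
  expect_equal(length(list.files(file.path(d, "masks"))), 21)
  expect_equal(nrow(read.csv(file.path(d, "clinical.csv"))), 3)
  expect_equal(nrow(read.csv(file.path(d, "cac.csv"))), 3)
  unlink(d, recursive = TRUE)
})
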