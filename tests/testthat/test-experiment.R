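test_that("Fisher combination matches its closed forms", {
  f <- fisherCombine(rep(1, 50))
  expect_equal(f$X, 0)
  expect_false(f$significant)
  f2 <- fisherCombine(rep(0.01, 50))
  expect_equal(f2$X, -2 * 50 * log(0.01), tolerance = 1e-12)
  expect_equal(f2$X, 460.52, tolerance = 1e-4)
  expect_equal(f2$df, 100)
  expect_equal(f2$critical, 135.81, tolerance = 1e-2)
  expect_true(f2$significant)
  expect_warning(fisherCombine(c(0, 0.5)), "clamped")
  expect_error(fisherCombine(c(-0.1, 0.5)))
})

test_that("trials keep the test set disjoint and reproducible", {
  ds <- tableDataset(n = 60, k = 6, beta_feat = 1, seed = 11)
  p <- stepwiseParams(inner_reps = 5, seed = 1)
  t1 <- runTrial(ds, p, trial_seed = 99)
  t2 <- runTrial(ds, p, trial_seed = 99)
  expect_true(t1$valid)
  expect_identical(t1$test_idx, t2$test_idx)
  expect_equal(t1$test_rho, t2$test_rho)
  expect_equal(length(t1$test_idx), round(0.15 * 60))
  t3 <- runTrial(ds, p, trial_seed = 100)
  expect_false(identical(t1$test_idx, t3$test_idx))
})

test_that("a strong planted signal yields positive test correlation", {
  ds <- tableDataset(n = 80, k = 6, beta_feat = 2, sd_noise = 0.5,
                     seed = 12)
  p <- stepwiseParams(inner_reps = 5, outer_reps = 10, seed = 3)
  ex <- runExperiment(ds, p)
  expect_equal(nrow(ex$trials), 10)
  expect_true(all(ex$trials$test_rho > 0.5))
  expect_true(ex$fisher$significant)
})

test_that("experiments use distinct test partitions across trials", {
  ds <- tableDataset(n = 60, k = 4, beta_feat = 1, seed = 13)
  p <- stepwiseParams(inner_reps = 3, outer_reps = 8, seed = 5)
  seeds <- spectRadiomics:::withLocalSeed(5, sample.int(
    .Machine$integer.max - 1, 8 + 200))
  parts <- lapply(seeds[1:8], function(s)
    runTrial(ds, p, s)$test_idx)
  expect_gt(length(unique(vapply(parts, paste, character(1),
                                 collapse = ","))), 1)
})

test_that("type-I error of the full protocol is near alpha on null data", {
  ## null: outcome independent of all candidates
  p <- stepwiseParams(inner_reps = 20, outer_reps = 50, alpha = 0.01)
  sig <- logical(8)
  for (r in seq_len(8)) {
    ds <- tableDataset(n = 60, k = 8, beta_feat = 0, beta_clin = 0,
                       seed = 300 + r)
    p$seed <- 400 + r
    ex <- runExperiment(ds, p)
    sig[r] <- ex$fisher$significant
  }
  ## at alpha = 0.01, two or more rejections in 8 replicates has
  ## probability < 0.3% under the null
  expect_lte(sum(sig), 1)
})

test_that("Fisher X grows with the planted effect and configuration", {
  p <- stepwiseParams(inner_reps = 8, outer_reps = 20, seed = 9)
  xs <- vapply(c(0, 0.6, 1.5), function(b) {
    ds <- tableDataset(n = 70, k = 6, beta_feat = b, beta_clin = 0.8,
                       seed = 21)
    runExperiment(ds, p)$fisher$X
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
})

test_that("combined >= clinical >= radiomics on a mixed-effect cohort", {
  ## outcome driven strongly by clinical risk, weakly by one feature
  set.seed(31)
  n <- 80
  cl <- sampleClinical(cohortParams(n_subjects = 1), n)
  fm <- matrix(rnorm(n * 6), n, 6,
               dimnames = list(NULL, paste0("feat", 1:6)))
  y <- 1.4 * (cl$age - 62) / 12 +
    0.8 * (cl$hyperlipidemia == "Yes") +
    0.6 * fm[, 1] + rnorm(n)
  p <- stepwiseParams(inner_reps = 8, outer_reps = 20, seed = 17)
  mk <- function(cols) {
    data <- if (identical(cols, "clinical")) cl
            else if (identical(cols, "radiomics")) as.data.frame(fm)
            else cbind(cl, as.data.frame(fm))
    list(y = y, data = data, design = buildDesign(data))
  }
  x_rad <- runExperiment(mk("radiomics"), p)$fisher$X
  x_cli <- runExperiment(mk("clinical"), p)$fisher$X
  x_com <- runExperiment(mk("combined"), p)$fisher$X
  expect_gte(x_cli, x_rad)
  expect_gte(x_com, x_cli)
})

test_that("invalid trials are flagged when no multi-term model exists", {
  ## a dataset whose outcome nothing can model under an impossible gate
  ds <- tableDataset(n = 50, k = 3, beta_feat = 0, seed = 41)
  p <- stepwiseParams(p_enter = 1e-9, p_remove = 1e-8, inner_reps = 3,
                      seed = 2)
  tr <- runTrial(ds, p, trial_seed = 7)
  expect_false(tr$valid)
  expect_match(tr$reason, "intercept-only")
})
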