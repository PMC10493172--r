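test_that("Berman categories follow the clinical interval edges", {
  expect_equal(bermanCategory(c(0, 5, 10, 10.5, 100, 100.01, 400, 1000,
                                2239)),
               c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 6L))
  expect_error(bermanCategory(-1), "nonnegative")
})

test_that("Spearman screening recovers perfect association", {
  set.seed(1)
  y <- rexp(25) * 100
  x <- cbind(same = y, anti = -y, noise = rnorm(25))
  res <- spearmanScreen(x, y)
  expect_equal(res$rho[res$feature_id == "same"], 1)
  expect_equal(res$rho[res$feature_id == "anti"], -1)
  expect_lt(res$p[res$feature_id == "same"], 1e-10)
  resd <- spearmanScreen(x, y, mode = "discrete")
  expect_gt(resd$rho[resd$feature_id == "same"], 0.8)
  expect_error(spearmanScreen(x, rep(1, 25)), "zero variance")
  expect_error(spearmanScreen(x[1:2, ], y[1:2]), "at least 3")
})

test_that("sample Spearman rho matches the rank-formula oracle", {
  set.seed(7)
  n <- 20
  reps <- 2000
  r_mine <- numeric(reps); r_oracle <- numeric(reps)
  for (k in seq_len(reps)) {
    x <- rnorm(n)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
    r_mine[k] <- spectRadiomics:::spearmanRho(x, y)
    d <- rank(x) - rank(y)                       # classic tie-free formula
    r_oracle[k] <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
  }
  expect_equal(r_mine, r_oracle, tolerance = 1e-12)
  ## population value ~ 6/pi asin(rho/2) for bivariate normals
  target <- 6 / pi * asin(0.25)
  expect_lt(abs(mean(r_mine) - target), 3 * sd(r_mine) / sqrt(reps) + 0.01)
})

test_that("exact permutation p-values are used below n = 10", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  r <- spectRadiomics:::spearmanRho(x, y)
  p_mine <- spectRadiomics:::spearmanP(x, y, r)
  p_ref <- cor.test(x, y, method = "spearman")$p.value
  expect_equal(p_mine, p_ref, tolerance = 1e-8)
})

test_that("BH step-up matches its defining thresholds", {
  expect_equal(bhFdr(c(0.001, 0.01, 0.03, 0.2), q = 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bhFdr(rep(1, 20))))
  expect_error(bhFdr(numeric(0)), "empty")
})

test_that("BH controls the FDR under a uniform null", {
  set.seed(10)
  m <- 56; reps <- 10000
  p <- matrix(runif(m * reps), reps, m)
  any_rej <- apply(p, 1, function(pv) any(bhFdr(pv, q = 0.05)))
  ## all nulls: FDR = P(any rejection) <= q
  fdr <- mean(any_rej)
  expect_lt(fdr, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("no feature survives FDR against CAC on a null cohort", {
  fs <- sharedNullFeatures()
  ch <- sharedNullCohort()
  sel <- memo("nullSelection", function() runSelectionPipeline(fs))
  rd <- SummarizedExperiment::rowData(fs)
  frac_pass <- vapply(segmentLabels(), function(seg) {
    rows <- rd$gl == 64 & rd$segment == seg &
      rd$feature_id %in% sel$features
    x <- t(featureValues(fs)[rows, , drop = FALSE])
    res <- spearmanScreen(x, outcomeForSegment(ch, seg))
    mean(res$q_pass, na.rm = TRUE)
  }, numeric(1))
  ## decoupled texture: the pass fraction stays within the FDR budget
  expect_lt(mean(frac_pass), 0.05 + 0.02)
})
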