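test_that("catalog stages reproduce the a priori arithmetic", {
  cat <- buildCatalog()
  s1 <- stage1DropAggregations(cat)
  expect_equal(nrow(s1), 215)
  expect_equal(length(attr(s1, "removed")), 272)
  expect_equal(nrow(stage1DropAggregations(s1)), 215)      # idempotent
  s2 <- stage2DropNonquantitative(s1)
  expect_equal(nrow(s2), 166)
  expect_equal(length(attr(s2, "removed")), 49)
  ## no texture descriptor touched at stage 2
  expect_false(any(attr(s2, "removed") %in%
                     cat$feature_id[cat$family %in%
                                      c("GLCM", "GLRLM", "GLSZM", "GLDZM",
                                        "NGTDM", "NGLDM")]))
})

test_that("stage 3 removes exactly the FBN-forced constants on a cohort", {
  mat <- shared166()
  s3 <- stage3DropConstant(mat)
  expect_equal(ncol(s3), 162)
  expect_setequal(attr(s3, "removed"),
                  c("ih_minimum", "ih_maximum", "ih_range",
                    "ngldm_3d_dependence_count_percentage"))
  ## an injected constant column is also caught
  mat2 <- cbind(mat, injected = rep(3.14, nrow(mat)))
  expect_true("injected" %in% attr(stage3DropConstant(mat2), "removed"))
  ## degenerate inputs refuse
  expect_error(stage3DropConstant(mat[1, , drop = FALSE]), "at least 2")
  expect_error(stage3DropConstant(mat[c(1, 1), ] * 0 + 1), "constant")
})

test_that("stage 4 drops one whole GLCM and GLRLM variety", {
  s3 <- stage3DropConstant(shared166())
  s4 <- stage4DedupVariety(s3)
  expect_equal(ncol(s4), 121)
  expect_equal(length(attr(s4, "removed")), 41)   # 25 GLCM + 16 GLRLM
  rem <- attr(s4, "removed")
  fam <- ifelse(grepl("^glcm", rem), "glcm", "glrlm")
  vari <- ifelse(grepl("_3d_avg_", rem), "avg", "merged")
  ## within a family, a single variety goes as a block
  expect_equal(length(unique(vari[fam == "glcm"])), 1)
  expect_equal(length(unique(vari[fam == "glrlm"])), 1)
  ## avg and merged track each other strongly across the cohort
  rho <- attr(s4, "diagonal_rho")
  expect_gt(median(rho$glcm, na.rm = TRUE), 0.9)
  expect_gt(mean(rho$glrlm >= 0.98, na.rm = TRUE), 0.9)
  expect_error(stage4DedupVariety(s4), "absent")
})

test_that("stage 5 finds the zone-family identity pairs plus duplicates", {
  s4 <- stage4DedupVariety(stage3DropConstant(shared166()))
  s5 <- stage5DropExactDuplicates(s4)
  pairs <- attr(s5, "pairs")
  key <- vapply(pairs, function(p) paste(sort(p), collapse = "|"),
                character(1))
  for (nm in c("zone_percentage", "gl_non_uniformity",
               "gl_non_uniformity_normalised"))
    expect_true(paste0("gldzm_3d_", nm, "|glszm_3d_", nm) %in% key)
  ## every found pair really is a rank-identical duplicate
  expect_true(all(lengths(pairs) == 2))
  ## injected duplicate column removed
  dup <- cbind(s4, dup_col = s4[, 1] * 2 + 5)   # monotone transform
  s5b <- stage5DropExactDuplicates(dup)
  expect_true("dup_col" %in% attr(s5b, "removed") ||
                colnames(s4)[1] %in% attr(s5b, "removed"))
  ## a table with no rho = 1 pair is unchanged
  set.seed(2)
  noise <- matrix(rnorm(200), 20, 10,
                  dimnames = list(NULL, paste0("f", 1:10)))
  expect_equal(ncol(stage5DropExactDuplicates(noise)), 10)
})

test_that("stage 6 removes features with tiny variance-to-mean ratio", {
  set.seed(5)
  m <- cbind(jitter_col = 5 + rnorm(30, sd = 1e-9),
             healthy = rnorm(30, 10, 3),
             zero_mean = rnorm(30, 0, 2))
  s6 <- stage6DropLowDynamicRange(m)
  expect_equal(attr(s6, "removed"), "jitter_col")
  expect_true(all(c("healthy", "zero_mean") %in% colnames(s6)))
})

test_that("stage 7 reproduces the hand-traced recursion", {
  ## hub pattern: f2 highly correlated with both f1 and f3, f1-f3 below
  ## the threshold, f4 independent -> the recursion keeps {f2, f4}
  set.seed(8)
  n <- 400
  repeat {
    f2 <- rnorm(n)
    f1 <- f2 + rnorm(n, sd = 0.20)
    f3 <- f2 + rnorm(n, sd = 0.20)
    f4 <- rnorm(n)
    m <- cbind(f1 = f1, f2 = f2, f3 = f3, f4 = f4)
    rho <- spectRadiomics:::absSpearman(m)
    if (rho["f1", "f2"] >= 0.95 && rho["f2", "f3"] >= 0.95 &&
          rho["f1", "f3"] < 0.95 && all(rho["f4", 1:3] < 0.95)) break
  }
  s7 <- stage7RecursivePrune(m)
  expect_setequal(colnames(s7), c("f2", "f4"))
  ## no high-correlation pair -> unchanged
  set.seed(9)
  noise <- matrix(rnorm(300), 30, 10,
                  dimnames = list(NULL, paste0("g", 1:10)))
  expect_equal(colnames(stage7RecursivePrune(noise)), paste0("g", 1:10))
  ## all mutually duplicated -> a single survivor, the first in order
  allsame <- cbind(a = f2, b = f2 + 1, c = 3 * f2)
  expect_equal(colnames(stage7RecursivePrune(allsame)), "a")
})

test_that("stage-7 survivors contain no high-correlation pair", {
  res <- memo("pipeline30", function()
    runSelectionPipeline(sharedFeatures()))
  tab <- res$table
  rho <- spectRadiomics:::absSpearman(tab)
  diag(rho) <- 0
  expect_lt(max(rho, na.rm = TRUE), 0.95)
})

test_that("the pipeline report tracks monotone survivor counts", {
  res <- memo("pipeline30", function()
    runSelectionPipeline(sharedFeatures()))
  counts <- stageCounts(res$report)$surviving
  expect_equal(counts[1:5], c(487, 215, 166, 162, 121))
  expect_true(all(diff(counts) <= 0))
  rem <- res$report@removed
  expect_false(any(duplicated(unlist(rem))))   # removed sets disjoint
  expect_equal(res$gl, 64L)
})

test_that("subject order does not change the selected feature set", {
  fs <- sharedFeatures()
  res1 <- memo("pipeline30", function() runSelectionPipeline(fs))
  perm <- rev(seq_len(ncol(fs)))
  res2 <- runSelectionPipeline(fs[, perm])
  expect_setequal(res1$features, res2$features)
})

test_that("gray-level selection prefers 64 among non-dominated levels", {
  fs <- memo("multiGL", function()
    extractFeatureTable(
      memo("cohort10", function()
        generateCohort(cohortParams(n_subjects = 10, seed = 33))),
      gls = c(4L, 64L, 512L)))
  s2 <- stage2DropNonquantitative(stage1DropAggregations(buildCatalog()))
  tabs <- lapply(c(4, 64, 512), function(g) {
    m <- spectRadiomics:::stackedFeatureMatrix(fs, g)
    m[, intersect(colnames(m), s2$feature_id), drop = FALSE]
  })
  names(tabs) <- c(4, 64, 512)
  sel <- selectGL(tabs)
  expect_equal(sel$gl, 64L)
  expect_equal(nrow(sel$diagnostics), 3)
  ## single GL returned trivially
  expect_equal(selectGL(tabs[2])$gl, 64L)
  ## identical diagnostics tie-break to the smaller level
  expect_equal(selectGL(list(`32` = tabs[[2]], `64` = tabs[[2]]),
                        preference = 128)$gl, 32L)
})
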