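test_that("uniform ROIs give the degenerate feature values", {
  f <- computeSegmentFeatures(array(5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)),
                              8)
  expect_equal(unname(f["glcm_3d_avg_joint_entropy"]), 0)
  expect_equal(unname(f["glcm_3d_merged_joint_entropy"]), 0)
  expect_equal(unname(f["glcm_3d_avg_joint_maximum"]), 1)
  expect_equal(unname(f["stat_variance"]), 0)
  expect_equal(unname(f["ih_mean"]), 1)       # constant ROI -> level 1
})

test_that("FBN forces histogram min/max/range and the NGLDM percentage", {
  set.seed(9)
  for (ng in c(4, 16, 64)) {
    g <- array(rnorm(343), c(7, 7, 7))
    msk <- array(stats::runif(343) < 0.7, c(7, 7, 7))
    msk[c(1, 2)] <- TRUE
    f <- computeSegmentFeatures(g, msk, ng)
    expect_equal(unname(f["ih_minimum"]), 1)
    expect_equal(unname(f["ih_maximum"]), ng)
    expect_equal(unname(f["ih_range"]), ng - 1)
    expect_equal(unname(f["ngldm_3d_dependence_count_percentage"]), 1)
  }
})

test_that("zone-marginal features coincide between GLSZM and GLDZM", {
  set.seed(13)
  g <- array(rnorm(216), c(6, 6, 6))
  msk <- array(stats::runif(216) < 0.8, c(6, 6, 6))
  msk[1] <- TRUE
  f <- computeSegmentFeatures(g, msk, 4)
  for (nm in c("zone_percentage", "gl_non_uniformity",
               "gl_non_uniformity_normalised", "low_gl_zone_emphasis",
               "high_gl_zone_emphasis", "gl_variance")) {
    expect_equal(unname(f[paste0("glszm_3d_", nm)]),
                 unname(f[paste0("gldzm_3d_", nm)]),
                 tolerance = 1e-12)
  }
})

test_that("undefined features surface as NaN sentinels, not dropped", {
  ## constant ROI: zero-variance moments and correlation terms undefined
  f <- computeSegmentFeatures(array(2, c(3, 3, 3)), array(TRUE, c(3, 3, 3)),
                              8)
  expect_true(is.nan(f[["stat_skewness"]]))
  expect_true(is.nan(f[["glcm_3d_merged_correlation"]]))
  expect_equal(length(f), 184)
  expect_false(any(is.na(f) & !is.nan(f)))
})

test_that("intensity statistics agree with direct formulas", {
  set.seed(3)
  x <- rnorm(100, 5, 2)
  g <- array(x, c(10, 10, 1))
  f <- computeSegmentFeatures(array(x, c(5, 5, 4)),
                              array(TRUE, c(5, 5, 4)), 8)
  expect_equal(unname(f["stat_mean"]), mean(x))
  expect_equal(unname(f["stat_variance"]), mean((x - mean(x))^2))
  expect_equal(unname(f["stat_energy"]), sum(x^2))
  expect_equal(unname(f["stat_root_mean_square"]), sqrt(mean(x^2)))
  expect_equal(unname(f["stat_median"]), median(x))
})
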