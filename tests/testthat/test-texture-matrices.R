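test_that("a uniform 2x2x2 ROI gives degenerate matrices", {
  droi <- discretizeFBN(array(1, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 4)
  m <- computeMatrices(droi)
  for (M in m$glcm) {
    expect_equal(sum(M) - M[1, 1], 0)      # all mass at (1,1)
    expect_true(M[1, 1] > 0)
  }
  expect_equal(m$glszm[1, 8], 1)           # one zone of size 8
  expect_equal(sum(m$glszm), 1)
  expect_equal(m$ngtdm$s, rep(0, 4))       # no gray-tone differences
})

test_that("all six matrix builders match brute-force enumeration", {
  set.seed(11)
  impl_offs <- spectRadiomics:::offsets13()
  n_cases <- 100
  for (case in seq_len(n_cases)) {
    ng <- sample(2:4, 1)
    lev <- randomROI(ng)
    droi <- asDroi(lev, ng)
    m <- computeMatrices(droi)
    dir <- sample(13, 1)                    # one random direction per case
    o <- impl_offs[dir, ]
    expect_equal(m$glcm[[dir]], bfGLCM(lev, ng, o),
                 ignore_attr = TRUE)
    expect_equal(m$glrlm[[dir]], bfGLRLM(lev, ng, o),
                 ignore_attr = TRUE)
    expect_equal(m$glszm, bfGLSZM(lev, ng), ignore_attr = TRUE)
    expect_equal(m$gldzm, bfGLDZM(lev, ng), ignore_attr = TRUE)
    expect_equal(m$ngtdm$n, bfNGTDM(lev, ng)$n)
    expect_equal(m$ngtdm$s, bfNGTDM(lev, ng)$s, tolerance = 1e-12)
    expect_equal(m$ngldm, bfNGLDM(lev, ng), ignore_attr = TRUE)
  }
})

test_that("GLSZM and GLDZM share per-gray-level zone totals", {
  set.seed(21)
  for (case in 1:20) {
    ng <- sample(2:4, 1)
    lev <- randomROI(ng)
    m <- computeMatrices(asDroi(lev, ng))
    expect_equal(rowSums(m$glszm), rowSums(m$gldzm))
  }
})

test_that("rotations by 90 degrees leave the computed features invariant", {
  set.seed(31)
  g <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  msk <- array(stats::runif(216) < 0.8, c(6, 6, 6))
  msk[1] <- TRUE
  f0 <- computeSegmentFeatures(g, msk, 4)
  rotz <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  f1 <- computeSegmentFeatures(rotz(g), rotz(msk), 4)
  expect_equal(f1, f0, tolerance = 1e-10)
  roty <- function(a) aperm(a, c(3, 2, 1))[dim(a)[3]:1, , , drop = FALSE]
  f2 <- computeSegmentFeatures(roty(g), roty(msk), 4)
  expect_equal(f2, f0, tolerance = 1e-10)
})
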