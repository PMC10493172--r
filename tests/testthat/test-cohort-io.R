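test_that("write-then-load round-trips a cohort", {
  ch <- fastCohort()
  d <- tempfile()
  writeCohort(ch, d)
  back <- loadCohort(d)
  expect_equal(subjectIds(back), subjectIds(ch))
  expect_equal(voxelSpacing(back), voxelSpacing(ch), tolerance = 1e-6)
  expect_equal(getImage(back, 1), getImage(ch, 1), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(getMask(back, 2, "LAD_MIM"), getMask(ch, 2, "LAD_MIM"))
  expect_equal(as.data.frame(clinicalData(back))$age,
               as.data.frame(clinicalData(ch))$age, tolerance = 1e-6)
  expect_equal(cacScores(back)$total, cacScores(ch)$total,
               tolerance = 1e-6)
  unlink(d, recursive = TRUE)
})

test_that("validation errors name the offending subject or file", {
  ch <- fastCohort()
  d <- tempfile()
  writeCohort(ch, d)
  cl <- read.csv(file.path(d, "clinical.csv"))
  cl$race[2] <- "Martian"
  write.csv(cl, file.path(d, "clinical.csv"), row.names = FALSE)
  expect_error(loadCohort(d), "S0002.*race|race.*Martian")
  writeCohort(ch, d)
  ## mask with mismatched shape
  bad <- RNifti::asNifti(array(1L, c(4, 4, 4)))
  RNifti::pixdim(bad) <- voxelSpacing(ch)
  badfile <- file.path(d, "masks", "S0001_MYO.nii.gz")
  RNifti::writeNifti(bad, badfile)
  expect_error(loadCohort(d), "shape mismatch.*S0001_MYO")
  unlink(d, recursive = TRUE)
  expect_error(loadCohort(tempfile()), "missing file")
})

test_that("segments map to their artery outcomes", {
  ch <- fastCohort()
  lad <- outcomeForSegment(ch, "LAD_MIM")
  expect_identical(lad, outcomeForSegment(ch, "LAD_17"))
  expect_equal(outcomeForSegment(ch, "MYO"),
               outcomeForSegment(ch, "LAD_MIM") +
                 outcomeForSegment(ch, "LCX_MIM") +
                 outcomeForSegment(ch, "RCA_MIM"))
  expect_equal(length(lad), length(ch))
  expect_error(outcomeForSegment(ch, "AORTA"))
})

test_that("cohort validity rejects inconsistent objects", {
  ch <- fastCohort()
  expect_error(methods::initialize(ch, ids = c("a", "a", "a")), "unique")
  bad_cac <- ch@cac
  bad_cac$total[1] <- bad_cac$total[1] + 5
  expect_error(methods::initialize(ch, cac = bad_cac), "total")
})
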