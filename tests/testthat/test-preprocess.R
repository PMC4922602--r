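test_that("QC computes global signal variance in percent units", {
  d <- makeDesign("binocular", nRuns = 7, seed = 1)
  m <- makeEffectModel(nVoxels = 20L, amplitude = 0, noiseSd = 0)
  b <- simulateSubject(d, m, rois = "R1", seed = 1)
  qc <- qcRuns(b)                       # noiseless: variance exactly 0
  expect_equal(qc$report$globalSignalVariance, rep(0, 7))
  expect_equal(qc$retained, 1:7)
  # an infinite threshold retains everything, drift or not
  b1 <- injectGlobalDrift(b, 1, 5)
  qcInf <- qcRuns(b1, preprocessParams(qcThreshold = Inf))
  expect_equal(qcInf$retained, 1:7)
  # all runs excluded is an error advising threshold review
  b2 <- b
  for (r in 1:7) b2 <- injectGlobalDrift(b2, r, 5)
  expect_error(qcRuns(b2), "qcThreshold")
})

test_that("voxel selection returns top-k by t, with the t > 0 fallback", {
  d <- makeDesign("binocular", nRuns = 7, seed = 1)
  # every ROI voxel responds to all conditions: all t > 0
  m <- makeEffectModel(nVoxels = 300L,
                       fractions = c(shared = 0.5, binoOnly = 0.5),
                       amplitude = 2, noiseSd = 1)
  b <- fixture("bigROI", function() simulateSubject(d, m, rois = "R1", seed = 2))
  # more responsive voxels than k -> exactly k returned
  vox <- selectVoxels(b, "R1", preprocessParams(kVoxels = 250L))
  expect_length(vox, 250)
  # fewer voxels with t > 0 than k -> exactly those returned
  mNull <- makeEffectModel(nVoxels = 100L, amplitude = 0, noiseSd = 1)
  bNull <- simulateSubject(makeDesign("binocular", nRuns = 7, seed = 1),
                           mNull, rois = "R1", seed = 3)
  voxN <- selectVoxels(bNull, "R1", preprocessParams(kVoxels = 250L))
  expect_lt(length(voxN), 100)
  expect_gt(length(voxN), 0)
  # selection equals the independent all-vs-fixation t ranking
  rd <- SummarizedExperiment::rowData(bNull)
  expect_true(all(rd$roi[voxN] == "R1"))
  expect_error(selectVoxels(bNull, "nope"), "no voxels")
})

test_that("a voxel with a much larger response ranks first", {
  d <- makeDesign("binocular", nRuns = 7, seed = 1)
  m <- makeEffectModel(nVoxels = 50L, fractions = c(shared = 1),
                       amplitude = 0.5, noiseSd = 1)
  b <- simulateSubject(d, m, rois = "R1", seed = 4)
  a <- SummarizedExperiment::assay(b, "bold")
  rd <- SummarizedExperiment::rowData(b)
  target <- which(rd$roi == "R1")[7]
  # rebuild that voxel with 10x the amplitude by adding 9 extra copies
  # of its expected response
  lab <- unlist(lapply(1:7, function(r)
    trLabels(S4Vectors::metadata(b)$design, r)))
  resp <- glossMVPA:::shiftSmooth(
    as.numeric(lab %in% c("mirror", "anti_mirror", "glossy")), 2L)
  a[target, ] <- a[target, ] + 9 * 0.5 * resp
  SummarizedExperiment::assay(b, "bold") <- a
  vox <- selectVoxels(b, "R1", preprocessParams(kVoxels = 10L))
  expect_equal(vox[1], target)
})

test_that("pattern extraction yields one normalized pattern per block", {
  d <- makeDesign("binocular", nRuns = 7, seed = 1)
  m <- makeEffectModel(nVoxels = 30L, fractions = c(binoOnly = 0.3),
                       amplitude = 1, noiseSd = 1)
  b <- fixture("extractSubject", function()
    simulateSubject(d, m, rois = "R1", seed = 5))
  ps <- extractPatterns(b, selectVoxels(b, "R1"))
  # 7 runs x 4 blocks per condition = 28 patterns per condition
  expect_equal(as.integer(table(conditionLabels(ps))), rep(28L, 4))
  expect_equal(ncol(ps), 112)
  # per-pattern across-voxel mean is zero after normalization
  pm <- SummarizedExperiment::assay(ps, "patterns")
  expect_lt(max(abs(colMeans(pm))), 1e-10)
  # z-scoring is per run per voxel on the raw time course
  a <- SummarizedExperiment::assay(b, "bold")
  v <- selectedVoxels(ps)[1]
  z <- scale(a[v, 1:200])
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  # deterministic given the dataset
  ps2 <- extractPatterns(b, selectedVoxels(ps))
  expect_identical(SummarizedExperiment::assay(ps),
                   SummarizedExperiment::assay(ps2))
})

test_that("extraction validates its preconditions", {
  d <- makeDesign("binocular", nRuns = 7, seed = 1)
  m <- makeEffectModel(nVoxels = 10L, amplitude = 0, noiseSd = 1)
  b <- simulateSubject(d, m, rois = "R1", seed = 6)
  expect_error(extractPatterns(b, integer(0)), "nonempty")
  expect_error(extractPatterns(b, 1:5, preprocessParams(shift = 3)),
               "multiple of TR")
  expect_error(extractPatterns(b, 1:5, runs = 1L), "two retained runs")
})

test_that("the timepoint-mean normalization alternative removes voxel run means", {
  d <- makeDesign("binocular", nRuns = 7, seed = 1)
  m <- makeEffectModel(nVoxels = 20L, amplitude = 0, noiseSd = 1)
  b <- simulateSubject(d, m, rois = "R1", seed = 7)
  ps <- extractPatterns(b, selectVoxels(b, "R1"),
                        preprocessParams(normalization = "timepoint_mean"))
  pm <- SummarizedExperiment::assay(ps, "patterns")
  runs <- runIds(ps)
  for (r in unique(runs))
    expect_lt(max(abs(rowMeans(pm[, runs == r]))), 1e-10)
})

test_that("pattern sets serialize to TSV with provenance", {
  d <- makeDesign("binocular", nRuns = 7, seed = 1)
  m <- makeEffectModel(nVoxels = 10L, amplitude = 0, noiseSd = 1)
  b <- simulateSubject(d, m, rois = "R1", seed = 8)
  ps <- extractPatterns(b, selectVoxels(b, "R1"))
  f <- file.path(withr::local_tempdir(), "patterns.tsv")
  writePatternTsv(ps, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), ncol(ps))
  expect_true(file.exists(paste0(f, ".json")))
})
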