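test_that("linearly separable clusters are fit with training accuracy 1", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40 * 5, mean = 2), 40, 5),
             matrix(rnorm(40 * 5, mean = -2), 40, 5))
  y <- rep(c("a", "b"), each = 40)
  m <- trainClassifier(x, y, positive = "a")
  expect_true(m$converged)
  expect_equal(mean(predictClassifier(m, x) == y), 1)
  expect_error(trainClassifier(x, rep("a", 80)), "single class")
})

test_that("the solver matches an independent SVM implementation", {
  # e1071/libsvm as the independent oracle: same hinge objective, same
  # cost and class weights; decision boundaries and predictions agree
  set.seed(2)
  for (rep in 1:10) {
    n1 <- 40; n2 <- 20
    x <- rbind(matrix(rnorm(n1 * 8, mean = 0.4), n1, 8),
               matrix(rnorm(n2 * 8, mean = -0.4), n2, 8))
    y <- rep(c("pos", "neg"), c(n1, n2))
    n <- n1 + n2
    m <- trainClassifier(x, y, positive = "pos", tol = 1e-4,
                         maxEpochs = 20000L)
    cw <- c(pos = n / (2 * n1), neg = n / (2 * n2))
    ref <- e1071::svm(x, factor(y, levels = c("pos", "neg")),
                      kernel = "linear", cost = 1, scale = FALSE,
                      class.weights = cw)
    xt <- matrix(rnorm(200 * 8), 200, 8)
    agree <- mean(predictClassifier(m, xt) == as.character(predict(ref, xt)))
    expect_gt(agree, 0.95)
  }
})

test_that("duplicating every pattern leaves a separable boundary unchanged", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20 * 6, mean = 3), 20, 6),
             matrix(rnorm(20 * 6, mean = -3), 20, 6))
  y <- rep(c("a", "b"), each = 20)
  m1 <- trainClassifier(x, y, positive = "a", tol = 1e-10,
                        maxEpochs = 100000L)
  m2 <- trainClassifier(rbind(x, x), c(y, y), positive = "a", tol = 1e-10,
                        maxEpochs = 100000L)
  expect_lt(max(abs(m1$w - m2$w)), 1e-8)
  expect_lt(abs(m1$b - m2$b), 1e-8)
})

test_that("class balancing halves the bias of imbalanced training but accuracy stays class-balanced", {
  # On pure noise the weighted SVM still over-predicts the majority
  # class; the independent implementation shows the same behaviour, so
  # the operative guarantee is the class-balanced accuracy, not the
  # raw prediction rate.
  set.seed(4)
  rateBal <- rateUnbal <- rateRef <- numeric(60)
  for (i in 1:60) {
    x <- matrix(rnorm(72 * 20), 72, 20)
    y <- rep(c("pos", "neg"), c(48, 24))
    xt <- matrix(rnorm(24 * 20), 24, 20)
    mb <- trainClassifier(x, y, positive = "pos", balance = TRUE)
    mu <- trainClassifier(x, y, positive = "pos", balance = FALSE)
    rateBal[i] <- mean(predictClassifier(mb, xt) == "pos")
    rateUnbal[i] <- mean(predictClassifier(mu, xt) == "pos")
    ref <- e1071::svm(x, factor(y, levels = c("pos", "neg")),
                      kernel = "linear", cost = 1, scale = FALSE,
                      class.weights = c(pos = 72 / 96, neg = 72 / 48))
    rateRef[i] <- mean(predict(ref, xt) == "pos")
  }
  expect_lt(mean(rateBal), mean(rateUnbal) - 0.05)  # balancing helps
  expect_equal(mean(rateBal), mean(rateRef), tolerance = 0.05)  # and matches libsvm
})

test_that("leave-one-run-out folds have the published train/test sizes", {
  cs <- glossContrasts()
  ps7 <- fixture("ps7", function() subjectPatterns(21, nRuns = 7))
  r <- crossValidate(ps7, cs$M_vs_A)
  # 7 runs: 24 training and 4 test patterns per condition per fold
  expect_equal(r@nTrain, rep(48L, 7))   # 24 x 2 conditions
  expect_equal(r@nTest, rep(8L, 7))     # 4 x 2 conditions
  ps10 <- fixture("ps10", function() subjectPatterns(22, nRuns = 10))
  r10 <- crossValidate(ps10, cs$M_vs_A)
  expect_equal(r10@nTrain, rep(72L, 10))  # 36 per condition
  # two-vs-one contrast: 12 test patterns per fold
  r2 <- crossValidate(ps7, cs$MA_vs_P)
  expect_equal(r2@nTest, rep(12L, 7))
  expect_equal(sum(confusionCounts(r2)), 84)
})

test_that("no fold tests on a run present in its training data", {
  # assertable on the fold bookkeeping: remove one run's patterns and
  # the per-fold sizes drop exactly as leave-one-run-out implies
  cs <- glossContrasts()
  ps <- fixture("ps7", function() subjectPatterns(21, nRuns = 7))
  r <- crossValidate(ps, cs$P_vs_F)
  expect_equal(sum(r@nTest), 56)               # every pattern tested once
  expect_equal(r@nTrain + r@nTest, rep(56L, 7))  # train = all minus test run
})

test_that("high-SNR structure-only simulations decode painted vs flat almost perfectly", {
  cs <- glossContrasts()
  m <- makeEffectModel(nVoxels = 40L, fractions = c(structure = 0.5),
                       amplitude = 10, noiseSd = 1)
  ps <- subjectPatterns(31, nRuns = 7, model = m)
  r <- crossValidate(ps, cs$P_vs_F)
  expect_gt(accuracy(r), 0.9)
})

test_that("feature order permutation leaves accuracy unchanged", {
  cs <- glossContrasts()
  ps <- fixture("ps7", function() subjectPatterns(21, nRuns = 7))
  r1 <- crossValidate(ps, cs$M_vs_A)
  set.seed(11)
  perm <- sample(nrow(ps))
  ps2 <- ps[perm, ]
  r2 <- crossValidate(ps2, cs$M_vs_A)
  expect_equal(accuracy(r1), accuracy(r2))
  expect_equal(confusionCounts(r1), confusionCounts(r2))
})

test_that("transfer onto the training set equals training accuracy", {
  cs <- glossContrasts()
  m <- makeEffectModel(nVoxels = 40L, fractions = c(binoOnly = 0.3),
                       amplitude = 3, noiseSd = 1)
  ps <- subjectPatterns(32, nRuns = 7, model = m)
  tr <- transferDecode(ps, cs$MA_vs_P, ps, cs$MA_vs_P)
  X <- patternMatrix(ps)
  cls <- glossMVPA:::contrastClass(conditionLabels(ps), cs$MA_vs_P)
  keep <- !is.na(cls)
  model <- trainClassifier(X[keep, ], cls[keep], positive = "pos")
  trainAcc <- glossMVPA:::balancedAccuracy(
    sum(predictClassifier(model, X[keep, ]) == "pos" & cls[keep] == "pos"),
    sum(predictClassifier(model, X[keep, ]) == "neg" & cls[keep] == "pos"),
    sum(predictClassifier(model, X[keep, ]) == "pos" & cls[keep] == "neg"),
    sum(predictClassifier(model, X[keep, ]) == "neg" & cls[keep] == "neg"))
  expect_equal(accuracy(tr), trainAcc)
})

test_that("transfer refuses mismatched voxel lists", {
  cs <- glossContrasts()
  ps <- fixture("ps7", function() subjectPatterns(21, nRuns = 7))
  ps2 <- subjectPatterns(23, nRuns = 7)
  expect_error(transferDecode(ps, cs$MA_vs_P, ps2, cs$F_vs_P),
               "voxel lists")
})

test_that("a run missing a contrast class is skipped with a warning", {
  cs <- glossContrasts()
  ps <- fixture("ps7", function() subjectPatterns(21, nRuns = 7))
  # drop the painted patterns of every run but run 1: the fold testing
  # run 1 then has no painted training patterns and must be skipped
  cd <- SummarizedExperiment::colData(ps)
  drop <- which(cd$run != 1 & cd$condition == "painted")
  psx <- ps[, setdiff(seq_len(ncol(ps)), drop)]
  expect_warning(r <- crossValidate(psx, cs$P_vs_F), "skipped")
  expect_equal(r@skippedFolds, 1L)
  expect_length(r@foldAccuracy, 6)
})
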