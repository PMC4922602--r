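test_that("d-prime follows the clipped z(H) - z(F) convention", {
  expect_equal(dprime(14, 14, 14, 14), 0)          # H = F
  expect_equal(dprime(10, 10, 5, 15), qnorm(0.5) - qnorm(0.25))
  # perfect 28/28 per class: both rates clipped by 1/(2N)
  expect_equal(dprime(28, 0, 0, 28), 2 * qnorm(55 / 56), tolerance = 1e-12)
  expect_equal(2 * qnorm(55 / 56), 4.200331, tolerance = 1e-6)
  # antisymmetric when the true class labels are swapped under fixed
  # predictions (hits<->fa, misses<->cr); invariant when the whole
  # contrast is relabelled (hits<->cr, misses<->fa)
  expect_equal(dprime(20, 8, 13, 15), -dprime(13, 15, 20, 8))
  expect_equal(dprime(20, 8, 13, 15), dprime(15, 13, 8, 20))
  expect_error(dprime(0, 0, 5, 5), "at least one")
})

test_that("gloss and 3D-structure indices are the stated d-prime differences", {
  expect_equal(computeIndices(c(MA_vs_P = 1, M_vs_A = 1, P_vs_F = 1)),
               c(gloss = 0, structure = 0))
  expect_equal(computeIndices(c(MA_vs_P = 1.0, M_vs_A = 0.2, P_vs_F = 0.8)),
               c(gloss = 0.8, structure = 0.6))
  expect_error(computeIndices(c(MA_vs_P = 1)), "must name")
})

test_that("index nulls are mean-zero over permuted-label simulations", {
  cs <- glossContrasts()
  psets <- binoNullCohort()[1:6]
  nl <- permutationNull(psets, nReps = 200, seed = 17, statistic = "index")
  expect_equal(mean(nl$gloss@reps), 0, tolerance = 0.05)
  expect_equal(mean(nl$structure@reps), 0, tolerance = 0.05)
})

test_that("group test is a one-tailed t against the baseline with Bonferroni", {
  expect_equal(groupTest(rep(0.53, 12), 0.53)$t, 0)
  expect_false(groupTest(rep(0.53, 12), 0.53)$significant)
  # values one SD above baseline, n = 12: t = mean/(sd/sqrt(n)) = sqrt(12)
  set.seed(8)
  v <- rnorm(12)
  v <- (v - mean(v)) / sd(v) + 1       # mean exactly 1 SD above 0
  expect_equal(groupTest(v, 0)$t, sqrt(12), tolerance = 1e-12)
  expect_equal(groupTest(rnorm(12), 0, nRois = 15)$alpha, 0.05 / 15)
  expect_error(groupTest(0.6, 0.5), "two subjects")
})

test_that("permutation nulls are unbiased, seeded and prefix-stable", {
  cs <- glossContrasts()
  psets <- binoNullCohort()
  nd1 <- permutationNull(psets, cs$M_vs_A, nReps = 100, seed = 5)
  nd2 <- permutationNull(psets, cs$M_vs_A, nReps = 100, seed = 5)
  expect_identical(nd1@reps, nd2@reps)             # bit-for-bit
  # rep i of a 100-rep call equals rep i of a longer call (same seed)
  nd3 <- permutationNull(psets, cs$M_vs_A, nReps = 300, seed = 5)
  expect_identical(nd1@reps[1:100, 1], nd3@reps[1:100, 1])
  expect_lt(abs(threshold95(nd1) - threshold95(nd3)), 0.005)
  expect_error(permutationNull(psets, cs$M_vs_A, nReps = 10), "at least 100")
})

test_that("the full-refit shuffling convention is also unbiased", {
  cs <- glossContrasts()
  psets <- binoNullCohort()[1:4]
  nd <- permutationNull(psets, cs$M_vs_A, nReps = 100, seed = 6,
                        shuffle = "full")
  expect_gt(mean(nd@reps), 0.47)
  expect_lt(mean(nd@reps), 0.53)
  nd2 <- permutationNull(psets, cs$MA_vs_P, nReps = 100, seed = 6,
                         shuffle = "full")
  expect_gt(mean(nd2@reps), 0.47)
  expect_lt(mean(nd2@reps), 0.53)
})

test_that("permutation thresholds shrink as one over the square root of n subjects", {
  cs <- glossContrasts()
  big <- fixture("scalingCohort", function()
    nullCohort(48L, "binocular", seed = 900L,
               model = nullModel(nVoxels = 24L)))
  margin <- vapply(c(3, 12, 48), function(n) {
    nd <- permutationNull(big[seq_len(n)], cs$M_vs_A, nReps = 400, seed = 13)
    threshold95(nd) - mean(nd@reps)
  }, numeric(1))
  expect_equal(margin[1] / margin[2], 2, tolerance = 0.35)
  expect_equal(margin[2] / margin[3], 2, tolerance = 0.35)
})

test_that("the two-by-ROI repeated-measures ANOVA has the design dfs", {
  set.seed(9)
  tab <- expand.grid(subject = 1:12, roi = paste0("r", 1:15),
                     index = c("gloss", "structure"))
  tab$value <- rnorm(nrow(tab), sd = 0.2)
  res <- compareIndicesAnova(tab)
  an <- res$anova
  expect_equal(an$df1[an$effect == "index"], 1)
  expect_equal(an$df2[an$effect == "index"], 11)
  expect_equal(an$df1[an$effect == "index:roi"], 14)
  expect_equal(an$df2[an$effect == "index:roi"], 154)
  expect_equal(nrow(res$tukey), choose(30, 2))
  # identical values everywhere: zero effect variance (F = 0/0)
  tab0 <- tab; tab0$value <- 1
  res0 <- compareIndicesAnova(tab0)
  expect_true(all(is.na(res0$anova$F) | res0$anova$F == 0))
  expect_error(compareIndicesAnova(tab[-1, ]), "complete")
})

test_that("a shifted ROI-by-index interaction is detected with good power", {
  set.seed(10)
  hits <- 0L
  for (rep in 1:60) {
    tab <- expand.grid(subject = 1:12, roi = paste0("r", 1:15),
                       index = c("gloss", "structure"))
    tab$value <- rnorm(nrow(tab), sd = 0.2)
    sel <- tab$roi == "r3" & tab$index == "gloss"
    tab$value[sel] <- tab$value[sel] + 0.4        # 2x the noise SD
    res <- compareIndicesAnova(tab)
    p <- res$anova$p[res$anova$effect == "index:roi"]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 60, 0.8)
})

test_that("Tukey cells flag the shifted pair", {
  set.seed(12)
  tab <- expand.grid(subject = 1:12, roi = paste0("r", 1:4),
                     index = c("gloss", "structure"))
  tab$value <- rnorm(nrow(tab), sd = 0.1)
  sel <- tab$roi == "r2" & tab$index == "gloss"
  tab$value[sel] <- tab$value[sel] + 1
  res <- compareIndicesAnova(tab)
  pair <- res$tukey[res$tukey$cell1 == "gloss:r2" &
                    res$tukey$cell2 == "structure:r2", ]
  expect_true(pair$significant)
})
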