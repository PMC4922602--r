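#' Signal-detection sensitivity of a decoding result
#'
#' Converts pooled confusion counts to d-prime, with the contrast's
#' positive class as "signal": `d' = z(H) - z(F)` where `H` and `F`
#' are the hit and false-alarm rates, each clipped to
#' `[1/(2N), 1 - 1/(2N)]` (N = test patterns of that class) so perfect
#' rates stay finite.
#'
#' @param hits,misses,fa,cr confusion counts, or pass a
#'   \linkS4class{DecodingResult} as `hits`.
#' @return d-prime.  Exchanging the true labels under fixed
#'   predictions (hits with fa, misses with cr) negates it.
#' @examples
#' dprime(28, 0, 0, 28)        # 2 * qnorm(55/56)
#' dprime(14, 14, 14, 14)      # 0
#' @export
dprime <- function(hits, misses = NULL, fa = NULL, cr = NULL) {
  if (is(hits, "DecodingResult")) {
    cc <- confusionCounts(hits)
    return(dprime(cc["hits"], cc["misses"], cc["fa"], cc["cr"]))
  }
  npos <- hits + misses; nneg <- fa + cr
  if (npos < 1 || nneg < 1) stop("each class needs at least one test pattern")
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  H <- clip(hits / npos, npos)
  F <- clip(fa / nneg, nneg)
  unname(qnorm(H) - qnorm(F))
}

#' Gloss and 3D-structure indices from per-contrast d-primes
#'
#' `gloss = d'(MA_vs_P) - d'(M_vs_A)`;
#' `structure = d'(P_vs_F) - d'(M_vs_A)`.
#' The mirror-vs-anti-mirror contrast serves as the baseline because
#' its two conditions share both appearance (glossy) and approximate
#' 3D structure.
#'
#' @param dprimes named numeric with at least `MA_vs_P`, `M_vs_A`,
#'   `P_vs_F` (e.g. from [dprime()] on three [crossValidate()]
#'   results).
#' @return named numeric `c(gloss = , structure = )`.
#' @export
computeIndices <- function(dprimes) {
  need <- c("MA_vs_P", "M_vs_A", "P_vs_F")
  if (!all(need %in% names(dprimes)))
    stop("dprimes must name MA_vs_P, M_vs_A and P_vs_F")
  c(gloss = unname(dprimes["MA_vs_P"] - dprimes["M_vs_A"]),
    structure = unname(dprimes["P_vs_F"] - dprimes["M_vs_A"]))
}

# Normalize a pattern-set collection to list(roi -> list(subject -> PatternSet))
asRoiCollection <- function(psets) {
  if (is(psets, "PatternSet")) return(list(ROI = list(psets)))
  stopifnot(is.list(psets), length(psets) > 0)
  if (is(psets[[1]], "PatternSet")) return(list(ROI = psets))
  psets
}

# Extract the decoding ingredients of one PatternSet once, so the
# permutation loop touches only plain matrices and vectors.
psetCore <- function(pset) {
  list(X = patternMatrix(pset),
       labels = conditionLabels(pset),
       run = runIds(pset))
}

# Leave-one-run-out decision values under the TRUE labels: every
# pattern of run r is scored by the classifier trained on the other
# runs' patterns of the contrast classes.  Returns one decision value
# per pattern (NA where a fold could not be trained).
cvDecisionValues <- function(core, contrast, balance, cost) {
  cls <- contrastClass(core$labels, contrast)
  f <- rep(NA_real_, nrow(core$X))
  for (r in unique(core$run)) {
    tr <- which(core$run != r & !is.na(cls))
    y <- ifelse(cls[tr] == "pos", 1L, -1L)
    if (length(unique(y)) < 2) next
    n <- length(y)
    wpos <- if (balance) n / (2 * sum(y > 0)) else 1
    wneg <- if (balance) n / (2 * sum(y < 0)) else 1
    fit <- svm_dcd(core$X[tr, , drop = FALSE], y,
                   cost * ifelse(y > 0, wpos, wneg))
    te <- which(core$run == r)
    f[te] <- core$X[te, , drop = FALSE] %*% fit$w + fit$b
  }
  f
}

# Confusion counts of fixed decision values against (shuffled) labels:
# the test set of a repetition is whichever patterns the shuffled
# labels place in the contrast.
scoreShuffled <- function(f, labels, contrast) {
  cls <- contrastClass(labels, contrast)
  sel <- which(!is.na(cls) & !is.na(f))
  pos <- cls[sel] == "pos"
  predPos <- f[sel] >= 0
  c(hits = sum(predPos & pos), misses = sum(!predPos & pos),
    fa = sum(predPos & !pos), cr = sum(!predPos & !pos))
}

# Permute condition labels within each run.  When `conditions` is
# given, only the labels of those conditions are permuted (among the
# patterns that carry them): the exchangeability null matched to a
# specific binary test.  Without it, all labels shuffle jointly.
shuffleWithinRun <- function(labels, run, conditions = NULL) {
  sel <- if (is.null(conditions)) rep(TRUE, length(labels))
         else labels %in% conditions
  for (r in unique(run)) {
    i <- which(sel & run == r)
    labels[i] <- labels[i[sample.int(length(i))]]
  }
  labels
}

cvCounts <- function(core, labels, contrast, balance, cost) {
  cls <- contrastClass(labels, contrast)
  keep <- which(!is.na(cls))
  y <- ifelse(cls[keep] == "pos", 1L, -1L)
  cv_loro_accuracy(core$X[keep, , drop = FALSE], y, core$run[keep],
                   cost = cost, balance = balance)
}

transferCounts <- function(trainCore, trainLabels, trainContrast,
                           testCore, testLabels, testContrast,
                           balance, cost) {
  ctr <- contrastClass(trainLabels, trainContrast)
  keep <- which(!is.na(ctr))
  y <- ifelse(ctr[keep] == "pos", 1L, -1L)
  n <- length(y)
  wpos <- if (balance) n / (2 * sum(y > 0)) else 1
  wneg <- if (balance) n / (2 * sum(y < 0)) else 1
  fit <- svm_dcd(trainCore$X[keep, , drop = FALSE], y,
                 cost * ifelse(y > 0, wpos, wneg))
  scoreShuffled(as.numeric(testCore$X %*% fit$w + fit$b),
                testLabels, testContrast)
}

#' Permutation null distribution of group-level decoding performance
#'
#' Builds the null distribution of the across-subject mean statistic
#' under within-run shuffling of the stimulus condition labels
#' (independently per repetition, subject and ROI, preserving the
#' run/fold structure), and returns its one-tailed empirical 95th
#' percentile.  With several ROIs, per-ROI thresholds are averaged
#' (the ROI-averaged baseline quoted under group figures).
#'
#' Two shuffling conventions are available.  The default,
#' `shuffle = "test"`, shuffles the condition labels *per test*:
#' classifiers are trained once on the true labels (leave-one-run-out
#' for a plain contrast; a single training-set fit for transfer) and
#' each repetition re-draws the labels of the test patterns within
#' each run, scoring the fixed decision values against them.  This is
#' the construction whose group-mean boundaries fall near 52-53%
#' for this design, and it makes transfer boundaries slightly lower
#' than CV boundaries (a fixed, class-biased model shrinks the
#' within-run accuracy variance).  `shuffle = "full"` instead retrains
#' the classifier on the shuffled labels in every repetition (the full
#' re-run reading); it is markedly slower and couples the folds
#' through their shared training data, widening the null.
#'
#' Reproducible bit for bit: repetition seeds are drawn once from
#' `seed`, so rep `i` of an `nReps = 100` call equals rep `i` of an
#' `nReps = 1000` call with the same seed.
#'
#' @param psets a list of per-subject \linkS4class{PatternSet}s, or a
#'   named list of such lists (one per ROI).
#' @param contrast the \linkS4class{Contrast} to decode (ignored for
#'   `statistic = "index"`).
#' @param nReps repetitions (>= 100).
#' @param seed master seed for the shuffle stream.
#' @param transferContrast if non-NULL, the test contrast of a
#'   transfer analysis: the classifier is trained on the `contrast`
#'   patterns and tested once on the `transferContrast` patterns (of
#'   `testPsets` if given, else of the same sets).
#' @param testPsets test-session pattern sets for cross-session
#'   transfer, matching the structure of `psets`.
#' @param statistic `"accuracy"` or `"index"` (group-mean gloss and
#'   3D-structure d-prime differences; both index terms use the same
#'   shuffled labels within a repetition).
#' @param shuffle `"test"` (default) or `"full"`; see Details.
#' @param balance,cost passed to the classifier.
#' @return a \linkS4class{NullDistribution}; for
#'   `statistic = "index"`, a named list of two (gloss, structure).
#' @export
permutationNull <- function(psets, contrast = NULL, nReps = 1000L, seed = 1L,
                            transferContrast = NULL, testPsets = NULL,
                            statistic = c("accuracy", "index"),
                            shuffle = c("test", "full"),
                            balance = TRUE, cost = 1) {
  statistic <- match.arg(statistic)
  shuffle <- match.arg(shuffle)
  nReps <- as.integer(nReps)
  if (nReps < 100) stop("nReps must be at least 100")
  rois <- asRoiCollection(psets)
  cores <- lapply(rois, function(subjects) lapply(subjects, psetCore))
  testCores <- if (!is.null(testPsets))
    lapply(asRoiCollection(testPsets), function(s) lapply(s, psetCore)) else NULL
  if (statistic == "index") {
    cs <- glossContrasts()
    idxContrasts <- cs[c("MA_vs_P", "M_vs_A", "P_vs_F")]
  } else if (is.null(contrast)) stop("a contrast is required")

  rng <- localRNG(seed)
  repSeeds <- sample.int(2147483646L, nReps)
  restoreRNG(rng)

  # accuracy nulls permute only the labels that enter the test (the
  # exchangeability null matched to the contrast); index nulls keep
  # the joint all-condition shuffle shared by their three terms
  cvConds <- if (statistic == "accuracy")
    c(contrast@positive, contrast@negative) else NULL
  teConds <- if (statistic == "accuracy" && !is.null(transferContrast))
    c(transferContrast@positive, transferContrast@negative) else NULL

  # decision values under the true labels, fixed across repetitions
  fvals <- NULL
  if (shuffle == "test") {
    fvals <- lapply(seq_along(cores), function(k) {
      lapply(seq_along(cores[[k]]), function(s) {
        core <- cores[[k]][[s]]
        if (statistic == "index") {
          lapply(idxContrasts, cvDecisionValues, core = core,
                 balance = balance, cost = cost)
        } else if (is.null(transferContrast)) {
          list(cv = cvDecisionValues(core, contrast, balance, cost))
        } else {
          cls <- contrastClass(core$labels, contrast)
          tr <- which(!is.na(cls))
          y <- ifelse(cls[tr] == "pos", 1L, -1L)
          n <- length(y)
          wpos <- if (balance) n / (2 * sum(y > 0)) else 1
          wneg <- if (balance) n / (2 * sum(y < 0)) else 1
          fit <- svm_dcd(core$X[tr, , drop = FALSE], y,
                         cost * ifelse(y > 0, wpos, wneg))
          tc <- if (is.null(testCores)) core else testCores[[k]][[s]]
          list(transfer = as.numeric(tc$X %*% fit$w + fit$b))
        }
      })
    })
  }

  nroi <- length(cores)
  acc <- array(NA_real_, c(nReps, nroi, if (statistic == "index") 2L else 1L))
  for (i in seq_len(nReps)) {
    rng <- localRNG(repSeeds[i])
    for (k in seq_len(nroi)) {
      subj <- cores[[k]]
      vals <- matrix(NA_real_, length(subj), dim(acc)[3])
      for (s in seq_along(subj)) {
        core <- subj[[s]]
        if (shuffle == "test") {
          fv <- fvals[[k]][[s]]
          if (statistic == "index") {
            lab <- shuffleWithinRun(core$labels, core$run)
            dp <- vapply(names(idxContrasts), function(cn) {
              cc <- scoreShuffled(fv[[cn]], lab, idxContrasts[[cn]])
              dprime(cc["hits"], cc["misses"], cc["fa"], cc["cr"])
            }, numeric(1))
            vals[s, ] <- computeIndices(dp)
          } else if (is.null(transferContrast)) {
            lab <- shuffleWithinRun(core$labels, core$run, cvConds)
            cc <- scoreShuffled(fv$cv, lab, contrast)
            vals[s, 1] <- balancedAccuracy(cc["hits"], cc["misses"],
                                           cc["fa"], cc["cr"])
          } else {
            tc <- if (is.null(testCores)) core else testCores[[k]][[s]]
            tlab <- shuffleWithinRun(tc$labels, tc$run, teConds)
            cc <- scoreShuffled(fv$transfer, tlab, transferContrast)
            vals[s, 1] <- balancedAccuracy(cc["hits"], cc["misses"],
                                           cc["fa"], cc["cr"])
          }
        } else {
          if (statistic == "index") {
            lab <- shuffleWithinRun(core$labels, core$run)
            dp <- vapply(idxContrasts, function(ct) {
              cc <- cvCounts(core, lab, ct, balance, cost)
              dprime(cc[3], cc[4], cc[5], cc[6])
            }, numeric(1))
            vals[s, ] <- computeIndices(dp)
          } else if (is.null(transferContrast)) {
            lab <- shuffleWithinRun(core$labels, core$run, cvConds)
            cc <- cvCounts(core, lab, contrast, balance, cost)
            vals[s, 1] <- balancedAccuracy(cc[3], cc[4], cc[5], cc[6])
          } else {
            # retrain on the shuffled labels, test once against the
            # real test labels
            lab <- shuffleWithinRun(core$labels, core$run, cvConds)
            tc <- if (is.null(testCores)) core else testCores[[k]][[s]]
            cc <- transferCounts(core, lab, contrast, tc, tc$labels,
                                 transferContrast, balance, cost)
            vals[s, 1] <- balancedAccuracy(cc["hits"], cc["misses"],
                                           cc["fa"], cc["cr"])
          }
        }
      }
      acc[i, k, ] <- colMeans(vals)
    }
    restoreRNG(rng)
  }

  scopeName <- if (statistic == "index") "index"
    else if (is.null(transferContrast)) contrast@name
    else paste0(contrast@name, "->", transferContrast@name)
  mkNull <- function(mat, what) {
    thr <- apply(mat, 2, quantile, probs = 0.95, names = FALSE)
    colnames(mat) <- names(rois)
    new("NullDistribution", reps = mat, perROI = thr,
        threshold95 = mean(thr), nReps = nReps, statistic = what,
        scope = scopeName, seed = as.integer(seed))
  }
  if (statistic == "index") {
    list(gloss = mkNull(matrix(acc[, , 1], nReps, nroi), "index"),
         structure = mkNull(matrix(acc[, , 2], nReps, nroi), "index"))
  } else {
    mkNull(matrix(acc[, , 1], nReps, nroi), "accuracy")
  }
}

#' Group-level one-sample test against a baseline
#'
#' One-sample t test of per-subject statistics against a scalar
#' baseline (e.g. a permutation threshold or chance), one-tailed
#' (greater), Bonferroni-corrected over the number of ROIs tested.
#'
#' @param values per-subject statistics.
#' @param baseline scalar baseline or a \linkS4class{NullDistribution}
#'   (its `threshold95` is used).
#' @param nRois number of simultaneous tests for Bonferroni.
#' @return list with `t`, `df`, `p` (one-tailed), `alpha`
#'   (0.05/nRois), `significant`.
#' @export
groupTest <- function(values, baseline, nRois = 1L) {
  if (is(baseline, "NullDistribution")) baseline <- threshold95(baseline)
  if (length(values) < 2) stop("need at least two subjects")
  alpha <- 0.05 / nRois
  if (sd(values) == 0) {
    # degenerate: all subjects identical
    t <- if (mean(values) == baseline) 0 else Inf * sign(mean(values) - baseline)
    p <- pt(t, df = length(values) - 1, lower.tail = FALSE)
    return(list(t = t, df = length(values) - 1, p = p, alpha = alpha,
                significant = p < alpha))
  }
  tt <- t.test(values, mu = baseline, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, alpha = alpha, significant = tt$p.value < alpha)
}

#' Two-by-ROI repeated-measures ANOVA on the indices, with Tukey HSD
#'
#' Within-subject two-factor ANOVA (index: gloss vs structure; ROI)
#' on a complete subject x ROI x index table, followed by Tukey
#' honest-significant-difference tests on the index-by-ROI cell means
#' using the interaction-stratum mean square.  For 12 subjects and 15
#' ROIs the design gives F dfs (1, 11) for index, (14, 154) for ROI
#' and the interaction.
#'
#' @param table data.frame with columns `subject`, `roi`, `index`
#'   (two levels), `value`; must be complete (no missing cells).
#' @return list with `anova` (data.frame of effects: F, df1, df2, p)
#'   and `tukey` (all pairwise cell comparisons: difference, q, p,
#'   significant at 0.05).
#' @export
compareIndicesAnova <- function(table) {
  need <- c("subject", "roi", "index", "value")
  if (!all(need %in% names(table))) stop("table must have subject/roi/index/value")
  table$subject <- factor(table$subject)
  table$roi <- factor(table$roi)
  table$index <- factor(table$index)
  nS <- nlevels(table$subject); nR <- nlevels(table$roi); nI <- nlevels(table$index)
  if (nrow(table) != nS * nR * nI || anyNA(table$value))
    stop("table must be complete, one value per subject x roi x index cell")

  if (var(table$value) == 0) {
    # degenerate: no variance anywhere, all effects exactly zero
    an <- data.frame(effect = c("index", "roi", "index:roi"), F = 0,
                     df1 = c(nI - 1, nR - 1, (nI - 1) * (nR - 1)),
                     df2 = c((nS - 1) * (nI - 1), (nS - 1) * (nR - 1),
                             (nS - 1) * (nI - 1) * (nR - 1)),
                     p = 1)
    cell <- aggregate(value ~ index + roi, table, mean)
    k <- nI * nR
    pairs <- t(combn(k, 2))
    tukey <- data.frame(
      cell1 = paste(cell$index, cell$roi, sep = ":")[pairs[, 1]],
      cell2 = paste(cell$index, cell$roi, sep = ":")[pairs[, 2]],
      diff = 0, q = 0, p = 1, significant = FALSE)
    return(list(anova = an, tukey = tukey, mse = 0,
                dfError = (nS - 1) * (nI - 1) * (nR - 1)))
  }

  fit <- aov(value ~ index * roi + Error(subject / (index * roi)), data = table)
  sm <- summary(fit)
  getF <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    err <- nrow(tab)  # residuals row is last
    data.frame(effect = term, F = tab$`F value`[i], df1 = tab$Df[i],
               df2 = tab$Df[err], p = tab$`Pr(>F)`[i])
  }
  an <- rbind(getF("Error: subject:index", "index"),
              getF("Error: subject:roi", "roi"),
              getF("Error: subject:index:roi", "index:roi"))
  rownames(an) <- NULL

  # Tukey HSD on the nI*nR cell means, interaction-stratum MSE
  itab <- sm[["Error: subject:index:roi"]][[1]]
  mse <- itab$`Mean Sq`[nrow(itab)]
  dfe <- itab$Df[nrow(itab)]
  cell <- aggregate(value ~ index + roi, table, mean)
  cell$name <- paste(cell$index, cell$roi, sep = ":")
  k <- nrow(cell)
  se <- sqrt(mse / nS)
  pairs <- t(combn(k, 2))
  diffs <- cell$value[pairs[, 1]] - cell$value[pairs[, 2]]
  q <- abs(diffs) / se
  p <- ptukey(q, nmeans = k, df = dfe, lower.tail = FALSE)
  tukey <- data.frame(cell1 = cell$name[pairs[, 1]],
                      cell2 = cell$name[pairs[, 2]],
                      diff = diffs, q = q, p = p, significant = p < 0.05)
  list(anova = an, tukey = tukey, mse = mse, dfError = dfe)
}
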