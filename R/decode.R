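#' The standard decoding contrasts
#'
#' Named binary contrasts used throughout the analysis:
#' `MA_vs_P` ({mirror, anti_mirror} vs painted), `M_vs_A`, `P_vs_F`,
#' `F_vs_P`, and `G_vs_M` (glossy vs matte, non-stereoscopic session).
#'
#' @return a named list of \linkS4class{Contrast} objects.
#' @export
glossContrasts <- function() {
  mk <- function(name, pos, neg) new("Contrast", name = name,
                                     positive = pos, negative = neg)
  list(
    MA_vs_P = mk("MA_vs_P", c("mirror", "anti_mirror"), "painted"),
    M_vs_A  = mk("M_vs_A", "mirror", "anti_mirror"),
    P_vs_F  = mk("P_vs_F", "painted", "flat"),
    F_vs_P  = mk("F_vs_P", "flat", "painted"),
    G_vs_M  = mk("G_vs_M", "glossy", "matte"))
}

#' Train a linear support-vector classifier
#'
#' Maximum-margin linear separator (hinge loss, soft-margin cost fixed
#' at 1 by default) solved by deterministic dual coordinate descent.
#' With `balance = TRUE` each class's misclassification penalty is
#' scaled by `n/(2 n_class)`, removing the bias that unequal training
#' class sizes would otherwise induce (the "j parameter" adjustment
#' for two-vs-one contrasts).
#'
#' @param x training patterns, rows = examples.
#' @param y labels: logical/factor/character with exactly two classes,
#'   or +1/-1.
#' @param positive which level of `y` is the positive class (default:
#'   first encountered).
#' @param balance scale per-class penalties by inverse class frequency.
#' @param cost soft-margin cost parameter C.
#' @param tol dual optimality tolerance (tighten for
#'   boundary-precision checks).
#' @param maxEpochs iteration cap for the solver.
#' @return list with `w` (weight vector), `b` (bias), `positive`,
#'   `negative`, and the solver diagnostics.  Decision values are
#'   `x %*% w + b`; ties (exactly 0) classify as positive.
#' @export
trainClassifier <- function(x, y, positive = NULL, balance = TRUE, cost = 1,
                            tol = 0.01, maxEpochs = 2000L) {
  x <- as.matrix(x)
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) < 2) stop("training data contain a single class")
  if (length(lev) > 2) stop("binary classification only")
  if (is.null(positive)) positive <- lev[1]
  if (!positive %in% lev) stop("'positive' is not a level of y")
  negative <- setdiff(lev, positive)
  yi <- ifelse(y == positive, 1L, -1L)
  n <- length(yi)
  wpos <- 1; wneg <- 1
  if (balance) {
    wpos <- n / (2 * sum(yi > 0))
    wneg <- n / (2 * sum(yi < 0))
  }
  Ci <- cost * ifelse(yi > 0, wpos, wneg)
  fit <- svm_dcd(x, yi, Ci, as.integer(maxEpochs), tol)
  list(w = as.numeric(fit$w), b = fit$b, positive = positive,
       negative = negative, converged = fit$converged, epochs = fit$epochs,
       cost = cost, balance = balance)
}

#' Predict with a trained linear classifier
#'
#' @param model result of [trainClassifier()].
#' @param x patterns, rows = examples.
#' @return character vector of predicted class labels (decision value
#'   ties go to the positive class).
#' @export
predictClassifier <- function(model, x) {
  f <- as.matrix(x) %*% model$w + model$b
  ifelse(f >= 0, model$positive, model$negative)
}

contrastClass <- function(labels, contrast) {
  ifelse(labels %in% contrast@positive, "pos",
         ifelse(labels %in% contrast@negative, "neg", NA))
}

# Class-balanced accuracy from pooled confusion counts: the mean of
# the two per-class correct rates.  Equal to the plain fraction
# correct whenever the test classes have equal counts; for the
# two-vs-one contrast it removes the residual majority-class
# prediction bias that per-class training weights do not fully
# eliminate.  Falls back to the plain fraction if a class is absent.
balancedAccuracy <- function(hits, misses, fa, cr) {
  npos <- hits + misses; nneg <- fa + cr
  if (npos == 0 || nneg == 0)
    return((hits + cr) / max(npos + nneg, 1))
  (hits / npos + cr / nneg) / 2
}

makeDecodingResult <- function(counts, foldAcc, nTrain, nTest, name, skipped) {
  conf <- c(hits = counts[3], misses = counts[4], fa = counts[5], cr = counts[6])
  names(conf) <- c("hits", "misses", "fa", "cr")
  new("DecodingResult",
      accuracy = balancedAccuracy(counts[3], counts[4], counts[5], counts[6]),
      foldAccuracy = foldAcc, confusion = conf,
      nTrain = as.integer(nTrain), nTest = as.integer(nTest),
      contrast = name, skippedFolds = as.integer(skipped))
}

#' Leave-one-run-out cross-validated decoding
#'
#' For each retained run, trains the linear SVM on all other runs'
#' patterns of the contrast classes (with balanced class weights when
#' class sizes are unequal) and tests on that run's patterns.
#' Accuracy and signal-detection confusion counts (positive class =
#' "signal") are pooled over folds.
#'
#' @param pset a \linkS4class{PatternSet}.
#' @param contrast a \linkS4class{Contrast}.
#' @param balance balance class weights (default TRUE; only matters
#'   for unequal class sizes).
#' @param cost soft-margin cost.
#' @return a \linkS4class{DecodingResult}.
#' @export
crossValidate <- function(pset, contrast, balance = TRUE, cost = 1) {
  X <- patternMatrix(pset)
  cls <- contrastClass(conditionLabels(pset), contrast)
  keep <- !is.na(cls)
  X <- X[keep, , drop = FALSE]
  cls <- cls[keep]
  run <- runIds(pset)[keep]
  runs <- unique(run)
  if (length(runs) < 2) stop("cross-validation needs at least two runs")

  counts <- c(0, 0, 0, 0, 0, 0)
  foldAcc <- numeric(0); nTrain <- integer(0); nTest <- integer(0)
  skipped <- 0L
  for (r in runs) {
    te <- run == r
    ytr <- cls[!te]
    if (length(unique(ytr)) < 2 || !any(te)) {
      warning(sprintf("fold for run %d skipped: a class is missing", r))
      skipped <- skipped + 1L
      next
    }
    model <- trainClassifier(X[!te, , drop = FALSE], ytr, positive = "pos",
                             balance = balance, cost = cost)
    pred <- predictClassifier(model, X[te, , drop = FALSE])
    truth <- cls[te]
    h <- sum(pred == "pos" & truth == "pos")
    m <- sum(pred == "neg" & truth == "pos")
    f <- sum(pred == "pos" & truth == "neg")
    c0 <- sum(pred == "neg" & truth == "neg")
    counts <- counts + c(h + c0, length(truth), h, m, f, c0)
    foldAcc <- c(foldAcc, (h + c0) / length(truth))
    nTrain <- c(nTrain, length(ytr)); nTest <- c(nTest, length(truth))
  }
  if (!length(foldAcc)) stop("all folds skipped")
  makeDecodingResult(counts, foldAcc, nTrain, nTest, contrast@name, skipped)
}

#' Cross-decoding transfer
#'
#' Trains a single classifier on all of `trainSet`'s patterns of
#' `trainContrast` and tests it once on all of `testSet`'s patterns of
#' `testContrast`, mapping the test contrast's positive class onto the
#' training contrast's positive class (e.g. glossy-trained classifiers
#' score mirror/anti-mirror patterns as "glossy").  Both sets must
#' come from the same voxels (same subject and ROI) so features align.
#'
#' @param trainSet,testSet \linkS4class{PatternSet}s sharing a voxel
#'   list; pass the same object for within-session transfer.
#' @param trainContrast,testContrast \linkS4class{Contrast}s.
#' @param balance,cost see [crossValidate()].
#' @return a \linkS4class{DecodingResult} (single "fold").
#' @export
transferDecode <- function(trainSet, trainContrast, testSet, testContrast,
                           balance = TRUE, cost = 1) {
  if (!identical(selectedVoxels(trainSet), selectedVoxels(testSet)))
    stop("train and test sets use different voxel lists")
  Xtr <- patternMatrix(trainSet)
  ctr <- contrastClass(conditionLabels(trainSet), trainContrast)
  Xtr <- Xtr[!is.na(ctr), , drop = FALSE]; ctr <- ctr[!is.na(ctr)]
  if (length(unique(ctr)) < 2) stop("training contrast classes absent")
  model <- trainClassifier(Xtr, ctr, positive = "pos", balance = balance,
                           cost = cost)
  Xte <- patternMatrix(testSet)
  cte <- contrastClass(conditionLabels(testSet), testContrast)
  Xte <- Xte[!is.na(cte), , drop = FALSE]; cte <- cte[!is.na(cte)]
  if (!length(cte)) stop("test contrast classes absent")
  pred <- predictClassifier(model, Xte)
  h <- sum(pred == "pos" & cte == "pos")
  m <- sum(pred == "neg" & cte == "pos")
  f <- sum(pred == "pos" & cte == "neg")
  c0 <- sum(pred == "neg" & cte == "neg")
  makeDecodingResult(c(h + c0, length(cte), h, m, f, c0),
                     (h + c0) / length(cte), nrow(Xtr), length(cte),
                     paste0(trainContrast@name, "->", testContrast@name), 0L)
}
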