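#' Construct PreprocessParams
#'
#' Defaults follow the analysis contract: runs whose whole-brain-mean
#' percent-signal time course has variance above 0.23 are excluded;
#' the top 250 voxels by the all-vs-fixation t contrast are retained
#' (all voxels with t > 0 if fewer); block windows are shifted by 4 s
#' for the hemodynamic delay; the 8 in-block TRs are averaged; each
#' block pattern's across-voxel mean is subtracted.
#'
#' @param qcThreshold QC variance threshold (percent-signal units).
#' @param kVoxels voxels to retain per ROI.
#' @param shift hemodynamic shift, seconds.
#' @param blockTRs TRs averaged per block.
#' @param normalization `"pattern_mean"` or `"timepoint_mean"`.
#' @return a \linkS4class{PreprocessParams}.
#' @export
preprocessParams <- function(qcThreshold = 0.23, kVoxels = 250L, shift = 4,
                             blockTRs = 8L,
                             normalization = c("pattern_mean", "timepoint_mean")) {
  new("PreprocessParams", qcThreshold = qcThreshold,
      kVoxels = as.integer(kVoxels), shift = shift,
      blockTRs = as.integer(blockTRs),
      normalization = match.arg(normalization))
}

#' Run-level quality control by global signal variance
#'
#' For each run, computes the whole-brain-mean time course, converts
#' it to percent signal change about its own mean, and takes its
#' variance.  Runs whose variance exceeds `params@qcThreshold` are
#' excluded.
#'
#' @param dataset a \linkS4class{BoldDataset}.
#' @param params a \linkS4class{PreprocessParams}.
#' @return list with `retained` (run indices), `excluded`, and
#'   `report` (data.frame of per-run variances and decisions).
#' @export
qcRuns <- function(dataset, params = preprocessParams()) {
  design <- S4Vectors::metadata(dataset)$design
  if (design@nRuns < 1) stop("dataset has no runs")
  a <- SummarizedExperiment::assay(dataset, "bold")
  runcol <- SummarizedExperiment::colData(dataset)$run
  gsv <- vapply(seq_len(design@nRuns), function(r) {
    m <- colMeans(a[, runcol == r, drop = FALSE])
    pct <- 100 * (m / mean(m) - 1)
    var(pct)
  }, numeric(1))
  retained <- which(gsv <= params@qcThreshold)
  if (!length(retained))
    stop("all runs excluded by QC; review the qcThreshold")
  list(retained = retained,
       excluded = setdiff(seq_len(design@nRuns), retained),
       report = data.frame(run = seq_len(design@nRuns),
                           globalSignalVariance = gsv,
                           retained = gsv <= params@qcThreshold))
}

# TR indices of a block's analysis window: onset shifted by the
# hemodynamic delay, clipped to the run.
shiftedWindow <- function(onsetTR, shiftTR, blockTRs, ntr) {
  w <- onsetTR + shiftTR + seq_len(blockTRs) - 1L
  w[w <= ntr]
}

shiftTRs <- function(design, params) {
  s <- params@shift / design@TR
  if (abs(s - round(s)) > 1e-9)
    stop("shift must be an integer multiple of TR")
  as.integer(round(s))
}

#' Select responsive voxels by the all-vs-fixation contrast
#'
#' Computes, per voxel of the ROI, the two-sample t statistic of the
#' (hemodynamically shifted) experimental-block TRs against the
#' fixation-block TRs over the retained runs, and returns the
#' `kVoxels` voxels with the highest t.  If fewer than `kVoxels`
#' voxels have t > 0, all voxels with t > 0 are returned.  Selection
#' uses only the all-vs-fixation contrast, never the to-be-decoded
#' one, so it does not bias cross-validation.
#'
#' @param dataset a \linkS4class{BoldDataset}.
#' @param roi ROI label present in the dataset's rowData.
#' @param params a \linkS4class{PreprocessParams}.
#' @param runs run indices to use (default: QC-retained runs).
#' @return integer voxel indices (rows of `dataset`), ordered by
#'   decreasing t.
#' @export
selectVoxels <- function(dataset, roi, params = preprocessParams(),
                         runs = NULL) {
  design <- S4Vectors::metadata(dataset)$design
  vox <- which(SummarizedExperiment::rowData(dataset)$roi == roi)
  if (!length(vox)) stop(sprintf("ROI '%s' has no voxels", roi))
  if (is.null(runs)) runs <- qcRuns(dataset, params)$retained
  sTR <- shiftTRs(design, params)
  a <- SummarizedExperiment::assay(dataset, "bold")
  runcol <- SummarizedExperiment::colData(dataset)$run
  ntr <- designLength(design)

  expCols <- integer(0); fixCols <- integer(0)
  for (r in runs) {
    ev <- blockOnsets(design, r)
    base <- (r - 1L) * ntr              # runs are contiguous column blocks
    for (i in seq_len(nrow(ev))) {
      w <- shiftedWindow(ev$onsetTR[i], sTR, params@blockTRs, ntr) + base
      if (ev$type[i] == "fixation") fixCols <- c(fixCols, w)
      else expCols <- c(expCols, w)
    }
  }
  xe <- a[vox, expCols, drop = FALSE]
  xf <- a[vox, fixCols, drop = FALSE]
  ne <- ncol(xe); nf <- ncol(xf)
  me <- rowMeans(xe); mf <- rowMeans(xf)
  ve <- rowSums((xe - me)^2) / (ne - 1)
  vf <- rowSums((xf - mf)^2) / (nf - 1)
  tstat <- (me - mf) / sqrt(ve / ne + vf / nf)
  tstat[!is.finite(tstat)] <- 0
  pos <- sum(tstat > 0)
  k <- if (pos >= params@kVoxels) params@kVoxels else pos
  ord <- order(tstat, decreasing = TRUE)
  vox[ord[seq_len(k)]]
}

#' Extract block-level multivoxel patterns
#'
#' Per retained run and voxel, z-scores the full time course; shifts
#' each block window by the hemodynamic delay; averages the in-block
#' TRs into one value per voxel per block; then normalizes each block
#' pattern by subtracting its across-voxel mean (removing baseline
#' differences between conditions and runs).  One labelled pattern per
#' experimental block.
#'
#' @param dataset a \linkS4class{BoldDataset}.
#' @param voxels voxel indices, e.g. from [selectVoxels()].
#' @param params a \linkS4class{PreprocessParams}.
#' @param runs run indices (default: QC-retained).
#' @return a \linkS4class{PatternSet} with one column per experimental
#'   block of the retained runs.
#' @export
extractPatterns <- function(dataset, voxels, params = preprocessParams(),
                            runs = NULL) {
  if (!length(voxels)) stop("voxels must be nonempty")
  design <- S4Vectors::metadata(dataset)$design
  qc <- NULL
  if (is.null(runs)) { qc <- qcRuns(dataset, params); runs <- qc$retained }
  if (length(runs) < 2)
    stop("at least two retained runs are required for cross-validation")
  sTR <- shiftTRs(design, params)
  a <- SummarizedExperiment::assay(dataset, "bold")
  runcol <- SummarizedExperiment::colData(dataset)$run
  ntr <- designLength(design)

  pats <- list(); cond <- character(0); runlab <- integer(0); blk <- integer(0)
  for (r in runs) {
    x <- a[voxels, runcol == r, drop = FALSE]
    mu <- rowMeans(x); s <- apply(x, 1, sd)
    s[s == 0] <- 1                      # constant voxel -> zeros, not NaN
    z <- (x - mu) / s
    ev <- blockOnsets(design, r)
    ev <- ev[ev$type != "fixation", , drop = FALSE]
    run_pats <- sapply(seq_len(nrow(ev)), function(i) {
      w <- shiftedWindow(ev$onsetTR[i], sTR, params@blockTRs, ntr)
      rowMeans(z[, w, drop = FALSE])
    })
    pats[[length(pats) + 1L]] <- run_pats
    cond <- c(cond, ev$type)
    runlab <- c(runlab, rep(r, nrow(ev)))
    blk <- c(blk, seq_len(nrow(ev)))
  }
  m <- do.call(cbind, pats)             # voxels x patterns
  if (params@normalization == "pattern_mean") {
    m <- sweep(m, 2, colMeans(m))
  } else {
    for (r in unique(runlab)) {
      j <- runlab == r
      m[, j] <- m[, j] - rowMeans(m[, j, drop = FALSE])
    }
  }
  md <- S4Vectors::metadata(dataset)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(patterns = m),
    colData = S4Vectors::DataFrame(condition = cond, run = runlab, block = blk),
    metadata = list(roi = unique(SummarizedExperiment::rowData(dataset)$roi[voxels]),
                    subject = md$subject, voxels = voxels, params = params,
                    qc = qc$report))
  new("PatternSet", se)
}

#' Write a PatternSet as TSV with a JSON provenance sidecar
#'
#' The TSV has one row per pattern: condition, run, block, then one
#' column per voxel.  The sidecar records subject, ROI, voxel indices
#' and preprocessing parameters.
#'
#' @param pset a \linkS4class{PatternSet}.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
writePatternTsv <- function(pset, path) {
  tab <- data.frame(condition = conditionLabels(pset), run = runIds(pset),
                    block = SummarizedExperiment::colData(pset)$block,
                    patternMatrix(pset), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    md <- S4Vectors::metadata(pset)
    p <- md$params
    prov <- list(subject = md$subject, roi = md$roi, voxels = md$voxels,
                 params = list(qcThreshold = p@qcThreshold, kVoxels = p@kVoxels,
                               shift = p@shift, blockTRs = p@blockTRs,
                               normalization = p@normalization))
    writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE), paste0(path, ".json"))
  }
  invisible(path)
}
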