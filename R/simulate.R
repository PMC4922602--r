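#' Construct an EffectModel
#'
#' @param nVoxels voxels per ROI (default 60; keeps toy subjects fast
#'   while leaving room for the top-k voxel selection to act).
#' @param fractions named population fractions (shared, monoOnly,
#'   binoOnly, structure); the remainder of the ROI is null.
#' @param amplitude response amplitude, percent signal change.
#' @param noiseSd i.i.d. noise SD, percent signal.
#' @param hrfLag hemodynamic delay, seconds.
#' @param baseline baseline BOLD level (arbitrary units).
#' @param ar1 lag-1 noise autocorrelation (0 = white noise).
#' @return an \linkS4class{EffectModel}.
#' @export
makeEffectModel <- function(nVoxels = 60L,
                            fractions = c(shared = 0, monoOnly = 0,
                                          binoOnly = 0, structure = 0),
                            amplitude = 1, noiseSd = 1, hrfLag = 4,
                            baseline = 100, ar1 = 0) {
  fr <- c(shared = 0, monoOnly = 0, binoOnly = 0, structure = 0)
  fr[names(fractions)] <- fractions
  new("EffectModel", nVoxels = as.integer(nVoxels), fractions = fr,
      amplitude = amplitude, noiseSd = noiseSd, hrfLag = hrfLag,
      baseline = baseline, ar1 = ar1)
}

# Toy brain geometry: ellipsoidal ROIs of exactly nVoxels voxels each,
# laid out along x in a rectangular "brain" grid; every other grid
# voxel is background.  Deterministic given the arguments.
makeToyBrain <- function(rois, nVoxels, voxelSize = c(2.5, 2.5, 3)) {
  nroi <- length(rois)
  # ellipsoid semi-axes (voxels) large enough to contain nVoxels
  r <- max(2, ceiling((nVoxels * 3 / (4 * pi) * 2) ^ (1 / 3)))
  spacing <- 2L * r + 3L
  dim <- c(nroi * spacing, 2L * r + 5L, 2L * r + 5L)
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  g$roi <- "background"
  for (i in seq_len(nroi)) {
    cx <- (i - 0.5) * spacing; cy <- dim[2] / 2 + 0.5; cz <- dim[3] / 2 + 0.5
    d2 <- ((g$x - cx) / r)^2 + ((g$y - cy) / r)^2 + ((g$z - cz) / r)^2
    idx <- order(d2)[seq_len(nVoxels)]
    g$roi[idx] <- rois[i]
  }
  list(grid = g, dim = dim, voxelSize = voxelSize)
}

# Delayed, 1-TR-ramp-smoothed boxcar: the package's hemodynamic model.
shiftSmooth <- function(box, lagTR) {
  n <- length(box)
  shifted <- c(rep(0, lagTR), box)[seq_len(n)]
  # 1-TR linear rise: average of the current and previous TR
  sm <- 0.5 * shifted + 0.5 * c(0, shifted[-n])
  sm
}

#' Simulate one subject's block-design BOLD dataset
#'
#' Generates a voxel-by-volume time series for every run of `design`
#' on a toy-brain grid with one ellipsoidal ROI per entry of `rois`.
#' Each ROI's voxels are partitioned into the ground-truth populations
#' of `model`; each voxel's time course is baseline plus
#' population-specific condition responses (boxcars delayed by the
#' hemodynamic lag with a 1-TR linear rise) plus i.i.d. Gaussian noise.
#' Population responses:
#' shared-gloss voxels respond to mirror, anti_mirror and glossy;
#' mono-only voxels to glossy; bino-only voxels to mirror and
#' anti_mirror; structure voxels carry one fixed voxelwise random
#' pattern for the disparity-3D conditions (mirror, painted,
#' anti_mirror) and an independent one for flat.
#'
#' The toy-brain geometry and the per-voxel population assignment and
#' pattern weights depend only on `seed`, not on the session, so the
#' binocular and non-stereoscopic datasets of a subject share voxels
#' when simulated with the same seed (as required for cross-session
#' transfer decoding); the noise stream is derived from both the seed
#' and the session.
#'
#' @param design an \linkS4class{ExperimentDesign}.
#' @param model an \linkS4class{EffectModel}.
#' @param rois character vector of ROI labels.
#' @param seed integer subject seed; identical seeds give identical
#'   datasets.
#' @param subject subject identifier stored in the metadata.
#' @return a \linkS4class{BoldDataset}.
#' @examples
#' des <- makeDesign("binocular", nRuns = 7, seed = 1)
#' mod <- makeEffectModel(fractions = c(binoOnly = 0.2), amplitude = 2)
#' bold <- simulateSubject(des, mod, rois = c("V3B", "LO"), seed = 1)
#' @export
simulateSubject <- function(design, model, rois = c("V3B", "LO", "pFs"),
                            seed = 1L, subject = sprintf("S%02d", seed)) {
  if (model@noiseSd < 0) stop("noiseSd must be nonnegative")
  brain <- makeToyBrain(rois, model@nVoxels)
  g <- brain$grid
  nvox <- nrow(g)
  ntr <- designLength(design)
  lagTR <- as.integer(round(model@hrfLag / design@TR))
  if (abs(lagTR * design@TR - model@hrfLag) > 1e-9)
    stop("hrfLag must be an integer multiple of TR")

  # population assignment + structure weights from the subject seed only
  rng <- localRNG(deriveSeed(seed, 101))
  pop <- rep("null", nvox)
  w3d <- numeric(nvox); wflat <- numeric(nvox)
  fr <- model@fractions
  for (roi in rois) {
    idx <- which(g$roi == roi)
    idx <- idx[sample.int(length(idx))]
    counts <- floor(fr * length(idx))
    labels <- rep(c("shared", "monoOnly", "binoOnly", "structure"), counts)
    if (length(labels)) pop[idx[seq_along(labels)]] <- labels
  }
  str_idx <- which(pop == "structure")
  w3d[str_idx] <- rnorm(length(str_idx))
  wflat[str_idx] <- rnorm(length(str_idx))
  restoreRNG(rng)

  # per-condition percent-signal amplitude, voxel x condition
  conds <- design@conditions
  amp <- matrix(0, nvox, length(conds), dimnames = list(NULL, conds))
  a <- model@amplitude
  respondsTo <- list(
    shared   = c("mirror", "anti_mirror", "glossy"),
    monoOnly = "glossy",
    binoOnly = c("mirror", "anti_mirror"))
  for (p in names(respondsTo)) {
    cc <- intersect(respondsTo[[p]], conds)
    if (length(cc)) amp[pop == p, cc] <- a
  }
  if (length(str_idx)) {
    c3d <- intersect(c("mirror", "painted", "anti_mirror"), conds)
    for (cc in c3d) amp[str_idx, cc] <- a * w3d[str_idx]
    if ("flat" %in% conds) amp[str_idx, "flat"] <- a * wflat[str_idx]
  }

  sessionId <- match(design@session, c("binocular", "nonstereoscopic"))
  rngNoise <- localRNG(deriveSeed(seed, 202, sessionId))
  runs <- vector("list", design@nRuns)
  for (r in seq_len(design@nRuns)) {
    reg <- sapply(conds, function(cc)
      shiftSmooth(as.numeric(trLabels(design, r) == cc), lagTR))
    signal <- amp %*% t(reg)                       # percent signal
    noise <- matrix(rnorm(nvox * ntr, sd = model@noiseSd), nvox, ntr)
    if (model@ar1 > 0) {
      phi <- model@ar1
      for (t in 2:ntr) noise[, t] <- phi * noise[, t - 1] +
          sqrt(1 - phi^2) * noise[, t]
    }
    runs[[r]] <- model@baseline * (1 + (signal + noise) / 100)
  }
  restoreRNG(rngNoise)

  bold <- do.call(cbind, runs)
  cd <- S4Vectors::DataFrame(
    run = rep(seq_len(design@nRuns), each = ntr),
    tr = rep(seq_len(ntr), design@nRuns),
    label = unlist(lapply(seq_len(design@nRuns), function(r) trLabels(design, r))))
  rd <- S4Vectors::DataFrame(g, population = pop)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bold = bold), rowData = rd, colData = cd,
    metadata = list(design = design, model = model, seed = as.integer(seed),
                    subject = subject, dim = brain$dim,
                    voxelSize = brain$voxelSize))
  new("BoldDataset", se)
}

#' Add a slow global drift to one run
#'
#' Adds a sinusoidal drift of the given percent amplitude (one cycle
#' per run) to every voxel of the chosen run, emulating the scanner
#' artifacts that the global-signal-variance QC screens for.
#'
#' @param dataset a \linkS4class{BoldDataset}.
#' @param run run index to contaminate.
#' @param amplitudePct drift amplitude, percent of baseline.
#' @return a modified copy of `dataset`.
#' @export
injectGlobalDrift <- function(dataset, run, amplitudePct) {
  if (amplitudePct < 0) stop("amplitudePct must be nonnegative")
  design <- S4Vectors::metadata(dataset)$design
  if (run < 1 || run > design@nRuns) stop("bad run index")
  if (amplitudePct == 0) return(dataset)
  ntr <- designLength(design)
  cols <- which(SummarizedExperiment::colData(dataset)$run == run)
  drift <- amplitudePct / 100 *
    S4Vectors::metadata(dataset)$model@baseline *
    sin(2 * pi * seq_len(ntr) / ntr)
  a <- SummarizedExperiment::assay(dataset, "bold")
  a[, cols] <- a[, cols] + matrix(drift, nrow(a), ntr, byrow = TRUE)
  SummarizedExperiment::assay(dataset, "bold") <- a
  dataset
}

#' Export a BoldDataset as NIfTI volumes plus a TSV event table
#'
#' Writes one 4-D NIfTI-1 file per run (grid x TRs) and the design's
#' block event table.  Requires the RNifti package.
#'
#' @param dataset a \linkS4class{BoldDataset}.
#' @param dir output directory (created if needed).
#' @return the written file paths, invisibly.
#' @export
writeBoldNifti <- function(dataset, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writeBoldNifti requires the RNifti package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- S4Vectors::metadata(dataset)
  g <- SummarizedExperiment::rowData(dataset)
  ntr <- designLength(md$design)
  files <- character(0)
  for (r in seq_len(md$design@nRuns)) {
    cols <- which(SummarizedExperiment::colData(dataset)$run == r)
    vol <- array(0, c(md$dim, ntr))
    idx <- cbind(g$x, g$y, g$z)
    a <- SummarizedExperiment::assay(dataset, "bold")[, cols]
    for (t in seq_len(ntr)) vol[cbind(idx, t)] <- a[, t]
    img <- RNifti::asNifti(vol, pixdim = c(md$voxelSize, md$design@TR))
    f <- file.path(dir, sprintf("%s_run%02d.nii", md$subject, r))
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  ev <- file.path(dir, sprintf("%s_events.tsv", md$subject))
  writeDesignTsv(md$design, ev)
  invisible(c(files, ev))
}
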