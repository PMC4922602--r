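#' @import methods
#' @importFrom stats var sd quantile qnorm rnorm runif t.test aov
#'   pt ptukey setNames aggregate
#' @importFrom utils write.table combn
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @useDynLib glossMVPA, .registration = TRUE
NULL

BINOCULAR_CONDITIONS <- c("mirror", "painted", "anti_mirror", "flat")
NONSTEREO_CONDITIONS <- c("glossy", "matte", "rough", "textured")

#' ExperimentDesign: block-design timing for one scanning session
#'
#' Encodes the run/block/TR grid of a gloss block-design session: 16
#' experimental blocks of 16 s per run (4 conditions x 4 repeats, in a
#' seeded pseudo-random order), seven 16-s fixation blocks (one at the
#' start, one at the end, and after experimental blocks 3, 5, 8, 11 and
#' 13), and a per-block response gap (2 s in the binocular session,
#' none in the non-stereoscopic session).  The scheduled run duration
#' is therefore 400 s (binocular) and 368 s (non-stereoscopic) at TR
#' 2 s.
#'
#' @slot session `"binocular"` or `"nonstereoscopic"`.
#' @slot TR repetition time, seconds.
#' @slot blockLen experimental block length in TRs (8, i.e. 16 s).
#' @slot responseGap response window appended to each experimental
#'   block, seconds.
#' @slot conditions the four condition labels of the session.
#' @slot blocksPerCondition repeats of each condition per run (4).
#' @slot fixationAfter experimental-block indices followed by a
#'   fixation block (besides the leading/trailing fixation).
#' @slot nRuns number of runs.
#' @slot blockOrder list (one character vector per run) giving the
#'   condition of each of the 16 experimental blocks.
#' @slot seed integer seed that generated the block orders.
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(session = "character", TR = "numeric", blockLen = "integer",
                 responseGap = "numeric", conditions = "character",
                 blocksPerCondition = "integer", fixationAfter = "integer",
                 nRuns = "integer", blockOrder = "list", seed = "integer"))

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (!object@session %in% c("binocular", "nonstereoscopic"))
    msg <- c(msg, "session must be 'binocular' or 'nonstereoscopic'")
  if (length(object@blockOrder) != object@nRuns)
    msg <- c(msg, "blockOrder must have one element per run")
  nblk <- length(object@conditions) * object@blocksPerCondition
  for (ord in object@blockOrder) {
    if (length(ord) != nblk)
      msg <- c(msg, sprintf("each run must have %d experimental blocks", nblk))
    tab <- table(factor(ord, levels = object@conditions))
    if (any(tab != object@blocksPerCondition))
      msg <- c(msg, "each condition must appear blocksPerCondition times per run")
  }
  if (length(msg)) msg else TRUE
})

#' EffectModel: ground-truth representational structure for simulation
#'
#' Describes the voxel populations of one simulated region of interest.
#' Fractions partition the ROI's voxels into populations implementing
#' the shared-subpopulation hypothesis for gloss processing:
#' \describe{
#'   \item{shared}{responds to gloss from either cue: mirror,
#'     anti-mirror (binocular session) and glossy (non-stereoscopic).}
#'   \item{monoOnly}{responds only to monocularly cued gloss (glossy).}
#'   \item{binoOnly}{responds only to binocularly cued gloss (mirror,
#'     anti-mirror).}
#'   \item{structure}{carries a multivoxel pattern that distinguishes
#'     disparity-defined 3D structure (one fixed random pattern for
#'     the 3D conditions mirror/painted/anti-mirror, a different one
#'     for flat).}
#' }
#' The remainder of the ROI and all background voxels are null (noise
#' only).  Amplitudes are percent signal change about baseline; noise
#' is i.i.d. Gaussian in percent signal units.
#'
#' @slot nVoxels voxels per ROI.
#' @slot fractions named nonnegative numeric (shared, monoOnly,
#'   binoOnly, structure), sum at most 1.
#' @slot amplitude percent-signal-change response amplitude (single
#'   value applied to every population).
#' @slot noiseSd i.i.d. Gaussian noise SD, percent signal.
#' @slot hrfLag hemodynamic delay, seconds (default 4).
#' @slot baseline baseline BOLD level, arbitrary units.
#' @slot ar1 lag-1 autocorrelation of the noise (0 = white, default).
#' @exportClass EffectModel
setClass("EffectModel",
  representation(nVoxels = "integer", fractions = "numeric",
                 amplitude = "numeric", noiseSd = "numeric",
                 hrfLag = "numeric", baseline = "numeric", ar1 = "numeric"))

setValidity("EffectModel", function(object) {
  msg <- character()
  need <- c("shared", "monoOnly", "binoOnly", "structure")
  if (!all(need %in% names(object@fractions)))
    msg <- c(msg, "fractions must be named shared/monoOnly/binoOnly/structure")
  if (any(object@fractions < 0) || sum(object@fractions) > 1 + 1e-12)
    msg <- c(msg, "fractions must be nonnegative and sum to at most 1")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be nonnegative")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@ar1 < 0 || object@ar1 >= 1) msg <- c(msg, "ar1 must be in [0,1)")
  if (length(msg)) msg else TRUE
})

#' BoldDataset: simulated voxel time series for one subject/session
#'
#' A \linkS4class{SummarizedExperiment} whose single assay `"bold"`
#' holds voxels (rows) by volumes (columns, all runs concatenated).
#' `rowData` carries the toy-brain geometry (grid indices `x`,`y`,`z`,
#' the `roi` label with `"background"` for non-ROI voxels, and the
#' ground-truth `population` assignment); `colData` carries `run`,
#' within-run TR index `tr`, and the stimulus `label` of each volume
#' (a condition name, `"fixation"` or `"gap"`).  `metadata` stores the
#' \linkS4class{ExperimentDesign}, the \linkS4class{EffectModel}, the
#' voxel size (mm), grid dimensions, subject id and seed.
#'
#' @exportClass BoldDataset
setClass("BoldDataset", contains = "SummarizedExperiment")

setValidity("BoldDataset", function(object) {
  msg <- character()
  md <- S4Vectors::metadata(object)
  if (is.null(md$design)) msg <- c(msg, "metadata$design is required")
  else {
    ntr <- designLength(md$design) * md$design@nRuns
    if (ncol(object) != ntr)
      msg <- c(msg, "column count must equal nRuns x TRs per run")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("roi", "x", "y", "z") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain roi, x, y, z")
  if (length(msg)) msg else TRUE
})

#' PatternSet: block-level multivoxel patterns
#'
#' A \linkS4class{SummarizedExperiment} whose assay `"patterns"` holds
#' selected voxels (rows) by block patterns (columns).  `colData`
#' carries `condition`, `run` and `block`; `metadata` carries the ROI
#' label, subject id, the selected voxel indices (into the source
#' \linkS4class{BoldDataset}), the \linkS4class{PreprocessParams} and
#' the QC report.  Values are z-units; after the per-pattern mean
#' subtraction every column mean is (numerically) zero.
#'
#' @exportClass PatternSet
setClass("PatternSet", contains = "SummarizedExperiment")

setValidity("PatternSet", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "run", "block") %in% colnames(cd)))
    msg <- c(msg, "colData must contain condition, run, block")
  if (length(msg)) msg else TRUE
})

#' PreprocessParams: pattern-extraction parameters
#'
#' @slot qcThreshold run-exclusion threshold on the variance of the
#'   whole-brain-mean percent-signal-change time course (0.23).
#' @slot kVoxels voxels retained per ROI by the all-vs-fixation
#'   t contrast (250; falls back to all voxels with t > 0).
#' @slot shift hemodynamic shift applied to block windows, seconds (4;
#'   must be an integer multiple of TR).
#' @slot blockTRs TRs averaged per block (8).
#' @slot normalization `"pattern_mean"` (default: subtract each block
#'   pattern's across-voxel mean) or `"timepoint_mean"` (subtract each
#'   voxel's across-pattern mean per run).
#' @exportClass PreprocessParams
setClass("PreprocessParams",
  representation(qcThreshold = "numeric", kVoxels = "integer",
                 shift = "numeric", blockTRs = "integer",
                 normalization = "character"))

setValidity("PreprocessParams", function(object) {
  msg <- character()
  if (object@kVoxels < 1L) msg <- c(msg, "kVoxels must be >= 1")
  if (!object@normalization %in% c("pattern_mean", "timepoint_mean"))
    msg <- c(msg, "normalization must be 'pattern_mean' or 'timepoint_mean'")
  if (length(msg)) msg else TRUE
})

#' Contrast: a binary decoding contrast
#'
#' @slot name short label, e.g. `"MA_vs_P"`.
#' @slot positive condition labels of the positive ("signal") class.
#' @slot negative condition labels of the negative class.
#' @exportClass Contrast
setClass("Contrast",
  representation(name = "character", positive = "character",
                 negative = "character"))

setValidity("Contrast", function(object) {
  msg <- character()
  if (!length(object@positive) || !length(object@negative))
    msg <- c(msg, "both classes must be nonempty")
  if (length(intersect(object@positive, object@negative)))
    msg <- c(msg, "classes must be disjoint")
  if (length(msg)) msg else TRUE
})

#' DecodingResult: cross-validated (or transfer) decoding performance
#'
#' @slot accuracy class-balanced accuracy from the fold-pooled
#'   confusion counts (mean of the two per-class correct rates; equal
#'   to the plain fraction correct when test class counts are equal,
#'   as in every one-vs-one contrast).
#' @slot foldAccuracy per-fold plain fractions correct.
#' @slot confusion named counts `hits`, `misses`, `fa`, `cr` with the
#'   contrast's positive class as "signal".
#' @slot nTrain,nTest training/test pattern counts per fold.
#' @slot contrast contrast name.
#' @slot skippedFolds number of folds skipped for missing classes.
#' @exportClass DecodingResult
setClass("DecodingResult",
  representation(accuracy = "numeric", foldAccuracy = "numeric",
                 confusion = "numeric", nTrain = "integer",
                 nTest = "integer", contrast = "character",
                 skippedFolds = "integer"))

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 1)
    msg <- c(msg, "accuracy must be in [0,1]")
  if (!all(c("hits", "misses", "fa", "cr") %in% names(object@confusion)))
    msg <- c(msg, "confusion must be named hits/misses/fa/cr")
  else if (sum(object@confusion) != sum(object@nTest))
    msg <- c(msg, "confusion counts must sum to the number of test patterns")
  if (length(msg)) msg else TRUE
})

#' NullDistribution: permutation null of a group-level statistic
#'
#' Stores, per shuffle repetition, the across-subject mean of the
#' statistic (accuracy or d-prime-difference index), per ROI, and the
#' one-tailed empirical 95th percentile.  When several ROIs are
#' analysed, `threshold95` is the across-ROI average of the per-ROI
#' thresholds, as in ROI-averaged figure baselines.
#'
#' @slot reps nReps x nROI matrix of group means per repetition.
#' @slot perROI per-ROI 95th percentiles.
#' @slot threshold95 across-ROI average threshold.
#' @slot nReps repetitions.
#' @slot statistic `"accuracy"` or `"index"`.
#' @slot scope description of the statistic (contrast or index name).
#' @slot seed master seed used for the shuffle stream.
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(reps = "matrix", perROI = "numeric", threshold95 = "numeric",
                 nReps = "integer", statistic = "character",
                 scope = "character", seed = "integer"))

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (nrow(object@reps) != object@nReps)
    msg <- c(msg, "reps must have nReps rows")
  thr <- apply(object@reps, 2, quantile, probs = 0.95, names = FALSE)
  if (max(abs(thr - object@perROI)) > 1e-8)
    msg <- c(msg, "perROI must be the empirical 95th percentiles of reps")
  if (length(msg)) msg else TRUE
})

#' Scene: geometry, eyes and illumination for stereo rendering
#'
#' @slot shape the procedural object returned by [makePotato()]:
#'   a star-shaped radial surface about its centroid plus a
#'   triangulated mesh.
#' @slot iod interocular distance, mm (65).
#' @slot viewDist viewing distance from the eyes to the object centre,
#'   mm (650).
#' @slot env equirectangular environment map, h x w x 3 array in
#'   [0,1], treated as at optical infinity.
#' @slot imageSize output image width/height in pixels.
#' @slot fovDeg field of view of the (shared) image plane, degrees;
#'   the object subtends about 7 degrees.
#' @exportClass Scene
setClass("Scene",
  representation(shape = "list", iod = "numeric", viewDist = "numeric",
                 env = "array", imageSize = "integer", fovDeg = "numeric"))

setValidity("Scene", function(object) {
  msg <- character()
  if (object@iod <= 0) msg <- c(msg, "iod must be positive (E_L != E_R)")
  if (length(dim(object@env)) != 3 || dim(object@env)[3] != 3)
    msg <- c(msg, "env must be an h x w x 3 array")
  if (any(object@imageSize < 8)) msg <- c(msg, "imageSize too small")
  if (length(msg)) msg else TRUE
})

#' StereoPair: a rendered left/right image pair
#'
#' @slot left,right h x w x 3 arrays in [0,1].
#' @slot condition one of mirror, painted, anti_mirror, flat.
#' @slot meta per-pixel surface-point bookkeeping per eye: hit masks,
#'   surface points `P` (mm), outward unit `normals`, unit
#'   environment-lookup directions `omega`, and for the flat condition
#'   which eye was duplicated.
#' @exportClass StereoPair
setClass("StereoPair",
  representation(left = "array", right = "array", condition = "character",
                 meta = "list"))

setValidity("StereoPair", function(object) {
  msg <- character()
  if (!identical(dim(object@left), dim(object@right)))
    msg <- c(msg, "left and right must have identical dimensions")
  if (!object@condition %in% BINOCULAR_CONDITIONS)
    msg <- c(msg, "condition must be mirror/painted/anti_mirror/flat")
  if (length(msg)) msg else TRUE
})

#' SearchlightParams: moving-sphere decoding parameters
#'
#' @slot radius sphere radius, mm (8).
#' @slot voxelSize voxel dimensions, mm (2.5, 2.5, 3).
#' @slot clusterMinVoxels minimum cluster extent, voxels (4; the
#'   grid-native analogue of a 25 mm^2 flat-map criterion at
#'   4 x 6.25 mm^2 in-plane).
#' @slot alpha per-voxel significance level (0.05, one-tailed).
#' @exportClass SearchlightParams
setClass("SearchlightParams",
  representation(radius = "numeric", voxelSize = "numeric",
                 clusterMinVoxels = "integer", alpha = "numeric"))

setValidity("SearchlightParams", function(object) {
  msg <- character()
  if (object@radius <= max(object@voxelSize))
    msg <- c(msg, "radius must exceed the largest voxel dimension")
  if (length(object@voxelSize) != 3) msg <- c(msg, "voxelSize must be length 3")
  if (length(msg)) msg else TRUE
})

#' StudyConfig: configuration of a full synthetic study
#'
#' @slot seed master seed (every downstream seed is derived from it).
#' @slot nSubjects number of subjects (12).
#' @slot runRange named list: run-count ranges per session.
#' @slot rois ROI labels.
#' @slot model the \linkS4class{EffectModel} applied to each ROI.
#' @slot nPerm permutation repetitions.
#' @slot outDir output directory.
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(seed = "integer", nSubjects = "integer", runRange = "list",
                 rois = "character", model = "EffectModel", nPerm = "integer",
                 outDir = "character"))

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (!length(object@seed)) msg <- c(msg, "a master seed is required")
  if (!all(c("binocular", "nonstereoscopic") %in% names(object@runRange)))
    msg <- c(msg, "runRange must name both sessions")
  if (length(msg)) msg else TRUE
})
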