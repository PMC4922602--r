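#' @rdname ExperimentDesign-class
#' @param design an `ExperimentDesign`.
#' @export
setGeneric("runDuration", function(design) standardGeneric("runDuration"))

#' @rdname ExperimentDesign-class
#' @export
setGeneric("designLength", function(design) standardGeneric("designLength"))

#' @rdname ExperimentDesign-class
#' @param run run index.
#' @export
setGeneric("trLabels", function(design, run) standardGeneric("trLabels"))

#' @rdname ExperimentDesign-class
#' @export
setGeneric("blockOnsets", function(design, run) standardGeneric("blockOnsets"))

#' @rdname PatternSet-class
#' @param x a `PatternSet`.
#' @export
setGeneric("patternMatrix", function(x) standardGeneric("patternMatrix"))

#' @rdname PatternSet-class
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname PatternSet-class
#' @export
setGeneric("runIds", function(x) standardGeneric("runIds"))

#' @rdname PatternSet-class
#' @export
setGeneric("selectedVoxels", function(x) standardGeneric("selectedVoxels"))

#' @rdname DecodingResult-class
#' @param object a `DecodingResult`.
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname DecodingResult-class
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))

#' @rdname NullDistribution-class
#' @param object a `NullDistribution`.
#' @export
setGeneric("threshold95", function(object) standardGeneric("threshold95"))

# -- Accessors ---------------------------------------------------------------

#' @rdname ExperimentDesign-class
#' @export
setMethod("runDuration", "ExperimentDesign", function(design) {
  nblk <- length(design@conditions) * design@blocksPerCondition
  nfix <- length(design@fixationAfter) + 2L
  nblk * (design@blockLen * design@TR + design@responseGap) +
    nfix * design@blockLen * design@TR
})

#' @rdname ExperimentDesign-class
#' @export
setMethod("designLength", "ExperimentDesign", function(design) {
  as.integer(round(runDuration(design) / design@TR))
})

#' @rdname PatternSet-class
#' @export
setMethod("patternMatrix", "PatternSet", function(x) {
  t(SummarizedExperiment::assay(x, "patterns"))
})

#' @rdname PatternSet-class
#' @export
setMethod("conditionLabels", "PatternSet", function(x) {
  as.character(SummarizedExperiment::colData(x)$condition)
})

#' @rdname PatternSet-class
#' @export
setMethod("runIds", "PatternSet", function(x) {
  as.integer(SummarizedExperiment::colData(x)$run)
})

#' @rdname PatternSet-class
#' @export
setMethod("selectedVoxels", "PatternSet", function(x) {
  S4Vectors::metadata(x)$voxels
})

#' @rdname DecodingResult-class
#' @export
setMethod("accuracy", "DecodingResult", function(object) object@accuracy)

#' @rdname DecodingResult-class
#' @export
setMethod("confusionCounts", "DecodingResult", function(object) object@confusion)

#' @rdname NullDistribution-class
#' @export
setMethod("threshold95", "NullDistribution", function(object) object@threshold95)

# -- show methods ------------------------------------------------------------

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf("ExperimentDesign: %s session, %d runs\n",
              object@session, object@nRuns))
  cat(sprintf("  TR %gs; %d experimental blocks/run (%d conditions x %d),",
              object@TR, length(object@conditions) * object@blocksPerCondition,
              length(object@conditions), object@blocksPerCondition))
  cat(sprintf(" %d fixation blocks\n", length(object@fixationAfter) + 2L))
  cat(sprintf("  scheduled run duration: %gs (%d TRs)\n",
              runDuration(object), designLength(object)))
})

setMethod("show", "EffectModel", function(object) {
  cat(sprintf("EffectModel: %d voxels/ROI, amplitude %g%%, noise SD %g%%\n",
              object@nVoxels, object@amplitude, object@noiseSd))
  fr <- object@fractions
  cat("  populations:",
      paste(sprintf("%s=%.2f", names(fr), fr), collapse = ", "),
      sprintf("(null=%.2f)\n", 1 - sum(fr)))
})

setMethod("show", "Contrast", function(object) {
  cat(sprintf("Contrast %s: {%s} vs {%s}\n", object@name,
              paste(object@positive, collapse = ", "),
              paste(object@negative, collapse = ", ")))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult [%s]: accuracy %.3f over %d folds (%d test patterns)\n",
              object@contrast, object@accuracy, length(object@foldAccuracy),
              sum(object@nTest)))
  cat("  confusion:", paste(sprintf("%s=%d", names(object@confusion),
                                    as.integer(object@confusion)),
                            collapse = ", "), "\n")
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution [%s, %s]: %d reps, %d ROI(s)\n",
              object@statistic, object@scope, object@nReps, ncol(object@reps)))
  cat(sprintf("  ROI-averaged one-tailed 95%% threshold: %.4f\n",
              object@threshold95))
})

setMethod("show", "StereoPair", function(object) {
  d <- dim(object@left)
  cat(sprintf("StereoPair [%s]: %d x %d px\n", object@condition, d[2], d[1]))
})

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: IOD %g mm, viewing distance %g mm, %d x %d px, fov %g deg\n",
              object@iod, object@viewDist, object@imageSize[1],
              object@imageSize[2], object@fovDeg))
})
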