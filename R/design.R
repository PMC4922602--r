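#' Construct a block-design session timing grid
#'
#' Builds the \linkS4class{ExperimentDesign} of one scanning session:
#' 16 experimental blocks per run (four conditions repeated four times,
#' in a seeded pseudo-random order per run), seven 16-s fixation blocks
#' (first, last, and after experimental blocks 3, 5, 8, 11, 13), TR
#' 2 s.  The binocular session appends a 2-s response window to every
#' experimental block, so a run schedules to 400 s; the
#' non-stereoscopic session has no response window and schedules to
#' 368 s.
#'
#' @param session `"binocular"` (conditions mirror, painted,
#'   anti_mirror, flat; 7-10 runs typical) or `"nonstereoscopic"`
#'   (glossy, matte, rough, textured; 8-10 runs typical).
#' @param nRuns number of runs.
#' @param seed integer seed for the per-run block orders.
#' @param allowAnyRuns allow run counts outside the session's typical
#'   range.
#' @return an \linkS4class{ExperimentDesign}.
#' @examples
#' d <- makeDesign("binocular", nRuns = 7, seed = 1)
#' runDuration(d)   # 400 seconds
#' @export
makeDesign <- function(session = c("binocular", "nonstereoscopic"),
                       nRuns = NULL, seed = 1L, allowAnyRuns = FALSE) {
  session <- match.arg(session)
  conds <- if (session == "binocular") BINOCULAR_CONDITIONS else NONSTEREO_CONDITIONS
  gap <- if (session == "binocular") 2 else 0
  range <- if (session == "binocular") c(7L, 10L) else c(8L, 10L)
  if (is.null(nRuns)) nRuns <- range[1]
  nRuns <- as.integer(nRuns)
  if (!allowAnyRuns && (nRuns < range[1] || nRuns > range[2]))
    stop(sprintf("nRuns = %d outside the %s session's range [%d, %d]; %s",
                 nRuns, session, range[1], range[2],
                 "set allowAnyRuns = TRUE to override"))
  rng <- localRNG(seed)
  order <- lapply(seq_len(nRuns), function(r) sample(rep(conds, 4L)))
  restoreRNG(rng)
  new("ExperimentDesign", session = session, TR = 2, blockLen = 8L,
      responseGap = gap, conditions = conds, blocksPerCondition = 4L,
      fixationAfter = c(3L, 5L, 8L, 11L, 13L), nRuns = nRuns,
      blockOrder = order, seed = as.integer(seed))
}

# Seed scoping: run `set.seed(seed)` inside a scope that restores the
# caller's RNG state afterwards, so library code never perturbs the
# global stream.
localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# Derive a child seed from a master seed and a stage/index pair; kept
# below 2^31 so it is always a valid R integer.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) x <- (x * 48271 + as.double(k) * 7919 + 1) %% 2147483647
  as.integer(x)
}

#' @rdname ExperimentDesign-class
#' @export
setMethod("blockOnsets", "ExperimentDesign", function(design, run) {
  stopifnot(run >= 1, run <= design@nRuns)
  blkTR <- design@blockLen
  gapTR <- as.integer(round(design@responseGap / design@TR))
  onsets <- integer(0); types <- character(0)
  tr <- 0L
  emit <- function(type, len) {
    onsets <<- c(onsets, tr + 1L); types <<- c(types, type); tr <<- tr + len
  }
  emit("fixation", blkTR)
  ord <- design@blockOrder[[run]]
  for (b in seq_along(ord)) {
    emit(ord[b], blkTR + gapTR)
    if (b %in% design@fixationAfter) emit("fixation", blkTR)
  }
  emit("fixation", blkTR)
  data.frame(block = seq_along(onsets), type = types, onsetTR = onsets,
             stimTRs = ifelse(types == "fixation", blkTR, blkTR),
             stringsAsFactors = FALSE)
})

#' @rdname ExperimentDesign-class
#' @export
setMethod("trLabels", "ExperimentDesign", function(design, run) {
  n <- designLength(design)
  lab <- rep("gap", n)
  ev <- blockOnsets(design, run)
  for (i in seq_len(nrow(ev)))
    lab[ev$onsetTR[i] + seq_len(design@blockLen) - 1L] <- ev$type[i]
  lab
})

#' Write a design's event table as TSV
#'
#' One row per block and run: run, block index, type (condition or
#' fixation), onset (s), duration (s).
#'
#' @param design an \linkS4class{ExperimentDesign}.
#' @param path output file.
#' @return the table, invisibly.
#' @export
writeDesignTsv <- function(design, path) {
  tabs <- lapply(seq_len(design@nRuns), function(r) {
    ev <- blockOnsets(design, r)
    data.frame(run = r, block = ev$block, type = ev$type,
               onset = (ev$onsetTR - 1) * design@TR,
               duration = ifelse(ev$type == "fixation",
                                 design@blockLen * design@TR,
                                 design@blockLen * design@TR + design@responseGap))
  })
  tab <- do.call(rbind, tabs)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
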