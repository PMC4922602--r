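#' Construct a StudyConfig
#'
#' @param seed master seed; all subject, noise and permutation seeds
#'   derive from it.
#' @param nSubjects subjects per session (12).
#' @param runRange named list of run-count ranges: subjects' run
#'   counts are drawn uniformly from these.
#' @param rois ROI labels simulated for every subject.
#' @param model the \linkS4class{EffectModel} applied to each ROI.
#' @param nPerm permutation repetitions for null thresholds.
#' @param outDir output directory for tables and figures.
#' @return a \linkS4class{StudyConfig}.
#' @export
studyConfig <- function(seed = 1L, nSubjects = 12L,
                        runRange = list(binocular = c(7L, 10L),
                                        nonstereoscopic = c(8L, 10L)),
                        rois = c("V3B", "LO", "pFs"),
                        model = makeEffectModel(), nPerm = 1000L,
                        outDir = tempfile("glossmvpa_study")) {
  new("StudyConfig", seed = as.integer(seed), nSubjects = as.integer(nSubjects),
      runRange = runRange, rois = rois, model = model,
      nPerm = as.integer(nPerm), outDir = outDir)
}

#' Read a StudyConfig from a YAML file
#'
#' Recognized top-level keys: `seed`, `n_subjects`, `run_range`
#' (`binocular`, `nonstereoscopic`: two-integer ranges), `rois`,
#' `model` (`n_voxels`, `fractions`, `amplitude`, `noise_sd`,
#' `hrf_lag`), `n_perm`, `out_dir`.
#'
#' @param path YAML file.
#' @return a \linkS4class{StudyConfig}.
#' @examples
#' cfg <- readStudyConfig(system.file("extdata", "example_study.yaml",
#'                                    package = "glossMVPA"))
#' cfg@nSubjects
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  model <- makeEffectModel(
    nVoxels = y$model$n_voxels %||% 60L,
    fractions = unlist(y$model$fractions) %||% c(shared = 0),
    amplitude = y$model$amplitude %||% 1,
    noiseSd = y$model$noise_sd %||% 1,
    hrfLag = y$model$hrf_lag %||% 4)
  studyConfig(
    seed = y$seed %||% 1L,
    nSubjects = y$n_subjects %||% 12L,
    runRange = list(
      binocular = as.integer(y$run_range$binocular %||% c(7L, 10L)),
      nonstereoscopic = as.integer(y$run_range$nonstereoscopic %||% c(8L, 10L))),
    rois = y$rois %||% c("V3B", "LO", "pFs"),
    model = model,
    nPerm = y$n_perm %||% 1000L,
    outDir = y$out_dir %||% tempfile("glossmvpa_study"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simulate all subjects of one session with seeded run counts.
simulateCohort <- function(config, session) {
  range <- config@runRange[[session]]
  rng <- localRNG(deriveSeed(config@seed, 41,
                             match(session, c("binocular", "nonstereoscopic"))))
  nRuns <- range[1] +
    sample.int(range[2] - range[1] + 1L, config@nSubjects, replace = TRUE) - 1L
  restoreRNG(rng)
  lapply(seq_len(config@nSubjects), function(s) {
    des <- makeDesign(session, nRuns = nRuns[s],
                      seed = deriveSeed(config@seed, 42, s,
                                        match(session, c("binocular",
                                                         "nonstereoscopic"))))
    simulateSubject(des, config@model, rois = config@rois,
                    seed = deriveSeed(config@seed, 43, s),
                    subject = sprintf("S%02d", s))
  })
}

# Per-ROI, per-subject pattern sets with the session's own voxel
# selection.  Returns list(roi -> list(subject -> PatternSet)).
cohortPatterns <- function(cohort, rois, params = preprocessParams()) {
  out <- lapply(rois, function(roi) {
    lapply(cohort, function(bold) {
      qc <- qcRuns(bold, params)
      vox <- selectVoxels(bold, roi, params, runs = qc$retained)
      extractPatterns(bold, vox, params, runs = qc$retained)
    })
  })
  names(out) <- rois
  out
}

#' Run the full synthetic study
#'
#' End-to-end orchestration on synthetic data: renders example stimuli
#' for the four binocular conditions plus a monocular glossy/matte
#' pair; simulates all subjects for both sessions; runs QC; decodes
#' the standard ROI contrasts (MA_vs_P, M_vs_A, P_vs_F binocular;
#' G_vs_M non-stereoscopic) with leave-one-run-out cross-validation;
#' computes per-subject d-prime gloss/3D-structure indices;
#' permutation-null thresholds per contrast; both within-binocular
#' transfer directions (MA_vs_P <-> F_vs_P) and both cross-session
#' transfer directions (G_vs_M <-> MA_vs_P, voxels selected from the
#' training session and applied to both); group t tests against the
#' thresholds with Bonferroni correction; and optionally a group
#' searchlight.  Tables (TSV) and figures (PNG) are written to
#' `config@outDir`.
#'
#' @param config a \linkS4class{StudyConfig}.
#' @param renderStimuli render and write the example stimuli.
#' @param doSearchlight run the per-subject searchlight and group
#'   cluster thresholding (the slowest stage).
#' @param searchlightContrast contrast name for the searchlight.
#' @return invisibly, a list with all result tables and objects.
#' @export
runStudy <- function(config, renderStimuli = TRUE, doSearchlight = FALSE,
                     searchlightContrast = "MA_vs_P") {
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cs <- glossContrasts()
  params <- preprocessParams()

  if (renderStimuli) stage("render", {
    shape <- makePotato(seed = deriveSeed(config@seed, 51))
    scene <- makeScene(shape, makeEnvMap("blobs",
                                         seed = deriveSeed(config@seed, 52)),
                       imageSize = c(64L, 64L))
    for (cond in BINOCULAR_CONDITIONS)
      writeStereoPair(renderCondition(scene, cond, seed = config@seed),
                      file.path(config@outDir, "stimuli"))
    mono <- makeMonocularPair(scene)
    png::writePNG(mono$glossy, file.path(config@outDir, "stimuli", "glossy.png"))
    png::writePNG(mono$matte, file.path(config@outDir, "stimuli", "matte.png"))
  })

  bino <- stage("simulate", simulateCohort(config, "binocular"))
  mono <- stage("simulate", simulateCohort(config, "nonstereoscopic"))

  qcTab <- stage("qc", do.call(rbind, lapply(seq_along(bino), function(s) {
    rbind(cbind(subject = s, session = "binocular",
                qcRuns(bino[[s]], params)$report),
          cbind(subject = s, session = "nonstereoscopic",
                qcRuns(mono[[s]], params)$report))
  })))
  write.table(qcTab, file.path(config@outDir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  binoPsets <- stage("patterns", cohortPatterns(bino, config@rois, params))
  monoPsets <- stage("patterns", cohortPatterns(mono, config@rois, params))

  roiContrasts <- list(MA_vs_P = "bino", M_vs_A = "bino", P_vs_F = "bino",
                       G_vs_M = "mono")
  decTab <- stage("decode", do.call(rbind, lapply(names(roiContrasts), function(cn) {
    psets <- if (roiContrasts[[cn]] == "bino") binoPsets else monoPsets
    do.call(rbind, lapply(config@rois, function(roi) {
      do.call(rbind, lapply(seq_len(config@nSubjects), function(s) {
        res <- crossValidate(psets[[roi]][[s]], cs[[cn]])
        data.frame(contrast = cn, roi = roi, subject = s,
                   accuracy = accuracy(res), dprime = dprime(res))
      }))
    }))
  })))
  write.table(decTab, file.path(config@outDir, "roi_decoding.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  idxTab <- stage("indices", do.call(rbind, lapply(config@rois, function(roi) {
    do.call(rbind, lapply(seq_len(config@nSubjects), function(s) {
      dp <- decTab[decTab$roi == roi & decTab$subject == s, ]
      dps <- setNames(dp$dprime, dp$contrast)
      ix <- computeIndices(dps)
      data.frame(subject = s, roi = roi,
                 index = c("gloss", "structure"), value = unname(ix))
    }))
  })))
  write.table(idxTab, file.path(config@outDir, "indices.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  nulls <- stage("permute", {
    n <- list(
      MA_vs_P = permutationNull(binoPsets, cs$MA_vs_P, config@nPerm,
                                seed = deriveSeed(config@seed, 61)),
      M_vs_A = permutationNull(binoPsets, cs$M_vs_A, config@nPerm,
                               seed = deriveSeed(config@seed, 62)),
      P_vs_F = permutationNull(binoPsets, cs$P_vs_F, config@nPerm,
                               seed = deriveSeed(config@seed, 63)),
      G_vs_M = permutationNull(monoPsets, cs$G_vs_M, config@nPerm,
                               seed = deriveSeed(config@seed, 64)))
    n
  })
  thrTab <- data.frame(contrast = names(nulls),
                       threshold95 = vapply(nulls, threshold95, numeric(1)))
  write.table(thrTab, file.path(config@outDir, "null_thresholds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  transfers <- stage("transfer", {
    withinDirs <- list(c("MA_vs_P", "F_vs_P"), c("F_vs_P", "MA_vs_P"))
    within <- do.call(rbind, lapply(withinDirs, function(d) {
      do.call(rbind, lapply(config@rois, function(roi) {
        do.call(rbind, lapply(seq_len(config@nSubjects), function(s) {
          res <- transferDecode(binoPsets[[roi]][[s]], cs[[d[1]]],
                                binoPsets[[roi]][[s]], cs[[d[2]]])
          data.frame(train = d[1], test = d[2], roi = roi, subject = s,
                     accuracy = accuracy(res))
        }))
      }))
    }))
    crossDirs <- list(c("G_vs_M", "MA_vs_P"), c("MA_vs_P", "G_vs_M"))
    cross <- do.call(rbind, lapply(crossDirs, function(d) {
      trainCohort <- if (d[1] == "G_vs_M") mono else bino
      testCohort <- if (d[1] == "G_vs_M") bino else mono
      do.call(rbind, lapply(config@rois, function(roi) {
        do.call(rbind, lapply(seq_len(config@nSubjects), function(s) {
          # voxels from the training session, applied to both sessions
          vox <- selectVoxels(trainCohort[[s]], roi, params)
          trainPs <- extractPatterns(trainCohort[[s]], vox, params)
          testPs <- extractPatterns(testCohort[[s]], vox, params)
          res <- transferDecode(trainPs, cs[[d[1]]], testPs, cs[[d[2]]])
          data.frame(train = d[1], test = d[2], roi = roi, subject = s,
                     accuracy = accuracy(res))
        }))
      }))
    }))
    rbind(within, cross)
  })
  write.table(transfers, file.path(config@outDir, "transfer.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  groupTab <- stage("group", do.call(rbind, lapply(names(nulls), function(cn) {
    do.call(rbind, lapply(config@rois, function(roi) {
      v <- decTab$accuracy[decTab$contrast == cn & decTab$roi == roi]
      gt <- groupTest(v, nulls[[cn]], nRois = length(config@rois))
      data.frame(contrast = cn, roi = roi, mean = mean(v),
                 t = gt$t, p = gt$p, significant = gt$significant)
    }))
  })))
  write.table(groupTab, file.path(config@outDir, "group_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sl <- NULL
  if (doSearchlight) sl <- stage("searchlight", {
    maps <- lapply(bino, searchlightMap, contrast = cs[[searchlightContrast]])
    res <- groupClusterThreshold(maps)
    write.table(res$clusters, file.path(config@outDir, "searchlight_clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  stage("figures", {
    plotFile <- function(name, expr) {
      grDevices::png(file.path(config@outDir, name), width = 900, height = 500)
      on.exit(grDevices::dev.off())
      expr
    }
    plotFile("roi_accuracy.png", {
      agg <- aggregate(accuracy ~ contrast + roi, decTab, mean)
      m <- matrix(agg$accuracy, nrow = length(unique(agg$contrast)),
                  dimnames = list(unique(agg$contrast), unique(agg$roi)))
      graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                        legend.text = rownames(m),
                        ylab = "decoding accuracy", xlab = "ROI")
      graphics::abline(h = 0.5)
      for (cn in names(nulls))
        graphics::abline(h = threshold95(nulls[[cn]]), lty = 3)
    })
    plotFile("indices.png", {
      agg <- aggregate(value ~ index + roi, idxTab, mean)
      m <- matrix(agg$value, nrow = 2,
                  dimnames = list(unique(agg$index), unique(agg$roi)))
      graphics::barplot(m, beside = TRUE, ylab = "d' difference", xlab = "ROI",
                        legend.text = rownames(m))
      graphics::abline(h = 0)
    })
  })

  invisible(list(decoding = decTab, indices = idxTab, thresholds = thrTab,
                 transfer = transfers, group = groupTab, qc = qcTab,
                 nulls = nulls, searchlight = sl, config = config))
}
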