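# Shared fixtures, built once per test run and memoized.  All fixtures
# are generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

nullModel <- function(nVoxels = 40L)
  makeEffectModel(nVoxels = nVoxels, fractions = c(shared = 0),
                  amplitude = 0, noiseSd = 1)

# One simulated subject with extracted patterns for one ROI.
subjectPatterns <- function(seed, session = "binocular", nRuns = 8L,
                            model = nullModel(), roi = "R1") {
  d <- makeDesign(session, nRuns = nRuns, seed = seed)
  b <- simulateSubject(d, model, rois = roi, seed = seed)
  extractPatterns(b, selectVoxels(b, roi))
}

# A cohort of null subjects (list of PatternSets, single ROI).
nullCohort <- function(n = 12L, session = "binocular", seed = 400L,
                       model = nullModel()) {
  range <- if (session == "binocular") 7:10 else 8:10
  set.seed(seed)
  nr <- sample(range, n, replace = TRUE)
  lapply(seq_len(n), function(s)
    subjectPatterns(seed + s, session, nr[s], model))
}

binoNullCohort <- function() fixture("binoNullCohort", function()
  nullCohort(12L, "binocular", seed = 400L))

monoNullCohort <- function() fixture("monoNullCohort", function()
  nullCohort(12L, "nonstereoscopic", seed = 700L))

# Independent finite-difference normal of the radial surface, used as
# the oracle for the renderer's reflection geometry.
oracleNormal <- function(shape, P, centre = c(0, 0, 650), h = 1e-4) {
  Fv <- function(x) {
    q <- x - centre
    r <- sqrt(sum(q^2))
    r - glossMVPA:::potatoRadius(shape, matrix(q / r, 1))
  }
  g <- vapply(1:3, function(k) {
    e <- c(0, 0, 0); e[k] <- h
    (Fv(P + e) - Fv(P - e)) / (2 * h)
  }, numeric(1))
  g / sqrt(sum(g^2))
}
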