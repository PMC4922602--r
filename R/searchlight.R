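#' Construct SearchlightParams
#'
#' @param radius sphere radius in mm (8).
#' @param voxelSize voxel dimensions in mm (2.5, 2.5, 3, as acquired).
#' @param clusterMinVoxels minimum surviving cluster extent in voxels
#'   (4: the grid-native analogue of a 25 mm^2 flat-map criterion,
#'   4 x 6.25 mm^2 in-plane).
#' @param alpha per-voxel one-tailed significance level.
#' @return a \linkS4class{SearchlightParams}.
#' @export
searchlightParams <- function(radius = 8, voxelSize = c(2.5, 2.5, 3),
                              clusterMinVoxels = 4L, alpha = 0.05) {
  new("SearchlightParams", radius = radius, voxelSize = voxelSize,
      clusterMinVoxels = as.integer(clusterMinVoxels), alpha = alpha)
}

#' Spherical neighborhoods on an anisotropic voxel grid
#'
#' For every in-mask voxel, the indices of the in-mask voxels whose
#' center-to-center Euclidean distance (in mm, respecting the
#' anisotropic voxel dimensions) is at most the sphere radius.  The
#' center voxel is always included, so neighborhoods are never empty;
#' at mask edges they shrink.
#'
#' @param coords n x 3 matrix/data.frame of grid indices of the
#'   in-mask voxels.
#' @param params a \linkS4class{SearchlightParams}.
#' @return list of integer vectors (indices into `coords` rows), one
#'   per voxel.
#' @export
sphereNeighborhoods <- function(coords, params = searchlightParams()) {
  coords <- as.matrix(coords)[, 1:3, drop = FALSE]
  if (!nrow(coords)) stop("mask is empty")
  vs <- params@voxelSize
  r <- params@radius
  # integer offsets within the sphere (the sphere "stencil")
  lim <- floor(r / vs)
  off <- as.matrix(expand.grid(dx = -lim[1]:lim[1], dy = -lim[2]:lim[2],
                               dz = -lim[3]:lim[3]))
  keep <- (off[, 1] * vs[1])^2 + (off[, 2] * vs[2])^2 + (off[, 3] * vs[3])^2 <= r^2
  off <- off[keep, , drop = FALSE]
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lut <- new.env(hash = TRUE, parent = emptyenv())
  ks <- key(coords)
  for (i in seq_len(nrow(coords))) assign(ks[i], i, envir = lut)
  lapply(seq_len(nrow(coords)), function(i) {
    nb <- sweep(off, 2, coords[i, ], `+`)
    hit <- mget(key(nb), envir = lut, ifnotfound = NA)
    sort(unlist(hit[!is.na(hit)], use.names = FALSE))
  })
}

#' Searchlight decoding map
#'
#' Moves a sphere through the in-mask voxels of a dataset; at each
#' center, extracts block patterns restricted to the neighborhood's
#' voxels (same shift/z-scoring/averaging/normalization rules as
#' [extractPatterns()], but no top-k voxel selection: the sphere is
#' the feature set), runs leave-one-run-out cross-validation for the
#' contrast, and writes the accuracy at the center.
#'
#' @param dataset a \linkS4class{BoldDataset}.
#' @param contrast a \linkS4class{Contrast}.
#' @param params a \linkS4class{SearchlightParams}.
#' @param preprocess a \linkS4class{PreprocessParams} (shift, block
#'   averaging, normalization, QC).
#' @param mask logical vector over dataset rows, or NULL for all
#'   voxels.
#' @param balance,cost classifier settings.
#' @return list with `accuracy` (per in-mask voxel), `coords` (their
#'   grid indices), `contrast`, `subject`.
#' @export
searchlightMap <- function(dataset, contrast, params = searchlightParams(),
                           preprocess = preprocessParams(), mask = NULL,
                           balance = TRUE, cost = 1) {
  rd <- SummarizedExperiment::rowData(dataset)
  if (is.null(mask)) mask <- rep(TRUE, nrow(dataset))
  vox <- which(mask)
  qc <- qcRuns(dataset, preprocess)
  if (length(qc$retained) < 2) stop("need at least two QC-retained runs")
  pset <- extractPatterns(dataset, vox, preprocess, runs = qc$retained)
  core <- psetCore(pset)
  coords <- as.matrix(rd[vox, c("x", "y", "z")])
  nbs <- sphereNeighborhoods(coords, params)

  cls <- contrastClass(core$labels, contrast)
  keep <- which(!is.na(cls))
  y <- ifelse(cls[keep] == "pos", 1L, -1L)
  run <- core$run[keep]
  X <- core$X[keep, , drop = FALSE]
  acc <- vapply(nbs, function(nb) {
    cc <- cv_loro_accuracy(X[, nb, drop = FALSE], y, run,
                           cost = cost, balance = balance)
    balancedAccuracy(cc[3], cc[4], cc[5], cc[6])
  }, numeric(1))
  list(accuracy = acc, coords = coords, contrast = contrast@name,
       subject = S4Vectors::metadata(dataset)$subject)
}

# 26-connectivity connected components over integer grid coordinates.
connectedComponents <- function(coords) {
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  lut <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(coords))) assign(key[i], i, envir = lut)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  comp <- integer(nrow(coords))
  cur <- 0L
  for (i in seq_len(nrow(coords))) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- sweep(off, 2, as.numeric(coords[v, ]), `+`)
      hit <- as.integer(unlist(mget(paste(nb[, 1], nb[, 2], nb[, 3]),
                                    envir = lut, ifnotfound = NA),
                               use.names = FALSE))
      hit <- hit[!is.na(hit)]
      hit <- hit[comp[hit] == 0]
      if (length(hit)) { comp[hit] <- cur; queue <- c(queue, hit) }
    }
  }
  comp
}

#' Group-level searchlight t map with cluster-size thresholding
#'
#' Per voxel, a one-sample t test of the subjects' accuracies against
#' chance (0.5), one-tailed.  Voxels with p below `alpha` form
#' candidate clusters under 26-connectivity; clusters smaller than
#' `clusterMinVoxels` are removed.
#'
#' @param maps list of per-subject searchlight maps (from
#'   [searchlightMap()]) on a common grid.
#' @param params a \linkS4class{SearchlightParams}.
#' @return list with `t`, `p` (per voxel), `coords`, `clusterId`
#'   (0 = not significant / removed) and `clusters` (data.frame:
#'   id, size in voxels, peak t, peak x/y/z).
#' @export
groupClusterThreshold <- function(maps, params = searchlightParams()) {
  if (length(maps) < 2) stop("need at least two subjects")
  coords <- maps[[1]]$coords
  for (m in maps)
    if (!identical(dim(m$coords), dim(coords)) ||
        any(m$coords != coords)) stop("subjects are not on a common grid")
  A <- sapply(maps, function(m) m$accuracy)   # voxels x subjects
  n <- ncol(A)
  mu <- rowMeans(A)
  s <- apply(A, 1, sd)
  tstat <- (mu - 0.5) / (s / sqrt(n))
  tstat[s == 0] <- 0
  p <- pt(tstat, df = n - 1, lower.tail = FALSE)
  sig <- which(p < params@alpha)

  clusterId <- integer(length(tstat))
  clusters <- data.frame(id = integer(0), size = integer(0), peakT = numeric(0),
                         x = integer(0), y = integer(0), z = integer(0))
  if (length(sig)) {
    comp <- connectedComponents(coords[sig, , drop = FALSE])
    keptId <- 0L
    for (cid in seq_len(max(comp))) {
      members <- sig[comp == cid]
      if (length(members) < params@clusterMinVoxels) next
      keptId <- keptId + 1L
      clusterId[members] <- keptId
      peak <- members[which.max(tstat[members])]
      clusters <- rbind(clusters, data.frame(
        id = keptId, size = length(members), peakT = tstat[peak],
        x = coords[peak, 1], y = coords[peak, 2], z = coords[peak, 3]))
    }
  }
  list(t = tstat, p = p, coords = coords, clusterId = clusterId,
       clusters = clusters)
}
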