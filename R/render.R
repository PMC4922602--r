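#' Procedural equirectangular environment maps
#'
#' Three families of seeded procedural spherical radiance maps
#' (smooth colour gradients, gradients with bright Gaussian blobs
#' acting as light sources, and a soft checker), used as the
#' illumination at optical infinity for specular rendering.
#'
#' @param type map family.
#' @param width,height map size in pixels (longitude x latitude).
#' @param seed integer seed.
#' @return h x w x 3 array in [0, 1].
#' @export
makeEnvMap <- function(type = c("blobs", "gradient", "checker"),
                       width = 256L, height = 128L, seed = 1L) {
  type <- match.arg(type)
  rng <- localRNG(deriveSeed(seed, 11))
  u <- matrix(rep(seq(0, 1, length.out = width), each = height), height, width)
  v <- matrix(rep(seq(0, 1, length.out = height), width), height, width)
  base <- array(0, c(height, width, 3))
  top <- runif(3, 0.3, 0.9); bottom <- runif(3, 0.05, 0.5)
  for (c in 1:3) base[, , c] <- top[c] * (1 - v) + bottom[c] * v
  if (type == "blobs") {
    nb <- 6L
    for (b in seq_len(nb)) {
      cu <- runif(1); cv <- runif(1, 0.1, 0.9); s <- runif(1, 0.01, 0.05)
      col <- runif(3, 0.6, 1)
      du <- pmin(abs(u - cu), 1 - abs(u - cu))   # wrap in longitude
      g <- exp(-((du^2 + (v - cv)^2) / (2 * s^2)))
      for (c in 1:3) base[, , c] <- base[, , c] + col[c] * g
    }
  } else if (type == "checker") {
    ch <- (floor(u * 8) + floor(v * 4)) %% 2
    for (c in 1:3) base[, , c] <- base[, , c] * (0.5 + 0.5 * ch)
  }
  restoreRNG(rng)
  pmin(base, 1)
}

# Evaluate the star-shaped radial field: dirs is n x 3 of unit
# directions (object frame); returns the surface radius per direction.
potatoRadius <- function(shape, dirs) {
  if (shape$amplitude == 0 || !length(shape$ampl))
    return(rep(shape$baseRadius, nrow(dirs)))
  proj <- dirs %*% t(shape$axes)                      # n x nModes
  s <- cos(sweep(sweep(proj, 2, shape$freq, `*`) * pi, 2, shape$phase, `+`))
  s <- as.numeric(s %*% shape$ampl) / sum(shape$ampl) # bounded in [-1, 1]
  shape$baseRadius * (1 + shape$amplitude * s)
}

#' Generate a random "potato" shape
#'
#' A radially distorted sphere: the radius field is a base radius
#' modulated by a seeded sum of smooth low-order angular cosine modes,
#' normalized so the relative distortion never exceeds `amplitude`.
#' The surface is star-shaped about its centre by construction and is
#' returned both as an exact radial field (used by the renderer) and
#' as a watertight latitude/longitude triangle mesh.
#'
#' @param seed integer seed; identical seeds give bitwise-identical
#'   meshes.
#' @param nModes number of angular modes (>= 1).
#' @param amplitude peak relative radius distortion, in [0, 0.5);
#'   larger values could drive the radius to zero and are rejected.
#' @param baseRadius base radius, mm (40 mm subtends about 7 degrees
#'   at a 650-mm viewing distance).
#' @param meshRes latitude bands of the triangulated mesh.
#' @return a list (class `"potatoShape"`) with the radial-field
#'   parameters and `vertices` / `faces` of the mesh.
#' @export
makePotato <- function(seed = 1L, nModes = 6L, amplitude = 0.15,
                       baseRadius = 40, meshRes = 48L) {
  if (nModes < 1) stop("nModes must be >= 1")
  if (amplitude < 0 || amplitude >= 0.5)
    stop("amplitude must be in [0, 0.5): larger distortions can drive the radius to zero (self-intersection)")
  rng <- localRNG(deriveSeed(seed, 21))
  axes <- matrix(rnorm(3 * nModes), nModes, 3)
  axes <- axes / sqrt(rowSums(axes^2))
  shape <- list(baseRadius = baseRadius, amplitude = amplitude,
                axes = axes, freq = sample(1:3, nModes, replace = TRUE),
                phase = runif(nModes, 0, 2 * pi),
                ampl = runif(nModes, 0.5, 1), seed = as.integer(seed))
  restoreRNG(rng)

  nu <- as.integer(meshRes); nv <- 2L * nu
  theta <- seq(0, pi, length.out = nu + 1L)
  phi <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  ring <- function(th) {
    d <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th), nv))
    d * potatoRadius(shape, d)
  }
  vertices <- rbind(c(0, 0, 1) * potatoRadius(shape, matrix(c(0, 0, 1), 1)),
                    do.call(rbind, lapply(theta[2:nu], ring)),
                    c(0, 0, -1) * potatoRadius(shape, matrix(c(0, 0, -1), 1)))
  idx <- function(i, j) 1L + (i - 1L) * nv + ((j - 1L) %% nv) + 1L  # ring i, lon j
  faces <- list()
  for (j in seq_len(nv)) faces[[length(faces) + 1L]] <- c(1L, idx(1, j), idx(1, j + 1))
  for (i in seq_len(nu - 2L)) for (j in seq_len(nv)) {
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  last <- nrow(vertices)
  for (j in seq_len(nv))
    faces[[length(faces) + 1L]] <- c(last, idx(nu - 1L, j + 1), idx(nu - 1L, j))
  shape$vertices <- vertices
  shape$faces <- do.call(rbind, faces)
  class(shape) <- "potatoShape"
  shape
}

#' Specular reflection of a view vector about a surface normal
#'
#' The physical law of specular reflection with `V` oriented from the
#' surface point toward the eye: `omega = 2 (n . V) n - V`.  The
#' reflected direction is unit length, lies in the plane spanned by
#' `n` and `V`, and makes the same angle with `n` as `V` does.
#'
#' @param V unit view vector(s), surface to eye: length-3 vector or
#'   n x 3 matrix.
#' @param n unit surface normal(s), same shape.
#' @return reflected unit direction(s), same shape as `V`.  Rows with
#'   `n . V <= 0` (back-facing) are returned as `NA`.
#' @export
reflectRay <- function(V, n) {
  vec <- is.null(dim(V))
  V <- rbind(V); n <- rbind(n)
  d <- rowSums(n * V)
  omega <- 2 * d * n - V
  omega[which(d <= 0), ] <- NA_real_   # back-facing samples excluded
  if (vec) omega[1, ] else omega
}

#' Assemble a rendering scene
#'
#' @param shape a [makePotato()] object.
#' @param env an environment map from [makeEnvMap()].
#' @param iod interocular distance, mm.
#' @param viewDist viewing distance to the object centre, mm.
#' @param imageSize c(width, height) pixels.
#' @param fovDeg image-plane field of view, degrees (the default
#'   frames the roughly 7-degree object).
#' @return a \linkS4class{Scene}.
#' @export
makeScene <- function(shape, env = makeEnvMap(), iod = 65, viewDist = 650,
                      imageSize = c(96L, 96L), fovDeg = 9) {
  new("Scene", shape = unclass(shape), iod = iod, viewDist = viewDist,
      env = env, imageSize = as.integer(imageSize), fovDeg = fovDeg)
}

normalizeRows <- function(m) m / sqrt(rowSums(m^2))

# Bilinear equirectangular lookup; dirs n x 3 unit vectors.
envLookup <- function(env, dirs) {
  h <- dim(env)[1]; w <- dim(env)[2]
  u <- (atan2(dirs[, 1], dirs[, 3]) / (2 * pi) + 0.5) * w
  v <- (acos(pmin(pmax(dirs[, 2], -1), 1)) / pi) * (h - 1) + 1
  u0 <- floor(u); fu <- u - u0
  v0 <- floor(v); fv <- v - v0
  v0 <- pmin(pmax(v0, 1), h); v1 <- pmin(v0 + 1, h)
  iu0 <- ((u0 - 1) %% w) + 1; iu1 <- (u0 %% w) + 1
  out <- matrix(NA_real_, nrow(dirs), 3)
  ok <- !is.na(u)
  for (c in 1:3) {
    ch <- env[, , c]
    out[ok, c] <-
      (1 - fu[ok]) * ((1 - fv[ok]) * ch[cbind(v0[ok], iu0[ok])] +
                      fv[ok] * ch[cbind(v1[ok], iu0[ok])]) +
      fu[ok] * ((1 - fv[ok]) * ch[cbind(v0[ok], iu1[ok])] +
                fv[ok] * ch[cbind(v1[ok], iu1[ok])])
  }
  out
}

# Cast one ray bundle (shared screen pixels) from an eye position at
# the star-shaped surface.  Returns hit mask, surface points and
# outward unit normals, all over the full pixel grid.
castRays <- function(scene, eye, nSteps = 48L, nBisect = 30L) {
  w <- scene@imageSize[1]; h <- scene@imageSize[2]
  C <- c(0, 0, scene@viewDist)
  half <- scene@viewDist * tan(scene@fovDeg * pi / 360)
  sx <- seq(-half, half, length.out = w)
  sy <- seq(half, -half, length.out = h)
  S <- cbind(rep(sx, each = h), rep(sy, w), scene@viewDist)  # column-major h x w
  D <- normalizeRows(sweep(S, 2, eye))
  n <- nrow(D)
  shape <- scene@shape
  Rmax <- shape$baseRadius * (1 + shape$amplitude) * 1.001

  EC <- C - eye
  b <- as.numeric(D %*% EC)
  disc <- b^2 - (sum(EC^2) - Rmax^2)
  hit0 <- disc > 0
  P <- matrix(NA_real_, n, 3); nrm <- matrix(NA_real_, n, 3)
  if (any(hit0)) {
    i <- which(hit0)
    tin <- b[i] - sqrt(disc[i]); tout <- b[i] + sqrt(disc[i])
    evalG <- function(tt) {
      p <- D[i, , drop = FALSE] * tt + matrix(eye, length(i), 3, byrow = TRUE)
      q <- sweep(p, 2, C)
      rr <- sqrt(rowSums(q^2))
      rr - potatoRadius(shape, q / rr)
    }
    # march to bracket the first surface crossing
    tlo <- tin; thi <- rep(NA_real_, length(i))
    glo <- evalG(tin)
    step <- (tout - tin) / nSteps
    tcur <- tin
    for (s in seq_len(nSteps)) {
      tnext <- tin + s * step
      gn <- evalG(tnext)
      fresh <- is.na(thi) & gn < 0
      thi[fresh] <- tnext[fresh]
      adv <- is.na(thi)
      tlo[adv] <- tnext[adv]
    }
    found <- !is.na(thi)
    ii <- which(found)
    if (length(ii)) {
      a <- tlo[ii]; bb <- thi[ii]
      sub <- i[ii]
      evalG2 <- function(tt) {
        p <- D[sub, , drop = FALSE] * tt + matrix(eye, length(sub), 3, byrow = TRUE)
        q <- sweep(p, 2, C)
        rr <- sqrt(rowSums(q^2))
        rr - potatoRadius(shape, q / rr)
      }
      for (s in seq_len(nBisect)) {
        mid <- (a + bb) / 2
        gm <- evalG2(mid)
        neg <- gm < 0
        bb[neg] <- mid[neg]; a[!neg] <- mid[!neg]
      }
      thit <- (a + bb) / 2
      Phit <- D[sub, , drop = FALSE] * thit + matrix(eye, length(sub), 3, byrow = TRUE)
      P[sub, ] <- Phit
      # outward normal: numerical gradient of |x - C| - r((x-C)/|x-C|)
      hstep <- 1e-3
      Fv <- function(x) {
        q <- sweep(x, 2, C); rr <- sqrt(rowSums(q^2))
        rr - potatoRadius(shape, q / rr)
      }
      grad <- sapply(1:3, function(k) {
        e <- c(0, 0, 0); e[k] <- hstep
        (Fv(sweep(Phit, 2, e, `+`)) - Fv(sweep(Phit, 2, e, `-`))) / (2 * hstep)
      })
      nrm[sub, ] <- normalizeRows(grad)
    }
  }
  list(hit = !is.na(P[, 1]), P = P, normals = nrm, D = D, w = w, h = h)
}

layerToImage <- function(vals, hit, h, w, background = 0.18) {
  img <- array(background, c(h, w, 3))
  for (c in 1:3) {
    ch <- matrix(background, h, w)
    ch[hit] <- vals[hit, c]
    img[, , c] <- ch
  }
  img
}

#' Render a stereo pair in one of the four disparity conditions
#'
#' Both eyes always cast rays from their true positions to the object
#' (the stereo view frustum of the surface itself is constant); the
#' conditions differ only in which reflected ray samples the
#' environment map at each surface point:
#' \describe{
#'   \item{mirror}{each eye's own reflected ray: physically correct
#'     specular reflection.}
#'   \item{painted}{the cyclopean (mid-point) eye's reflected ray for
#'     both eyes: reflections get the surface's own disparity, like a
#'     texture painted on.}
#'   \item{anti_mirror}{the two eyes' reflected rays are swapped at
#'     each surface point.}
#'   \item{flat}{the mirror image of one eye (chosen by a seeded coin
#'     flip, recorded in `meta$flatEye`) shown to both eyes: no
#'     binocular disparity at all.}
#' }
#'
#' @param scene a \linkS4class{Scene}.
#' @param condition one of `"mirror"`, `"painted"`, `"anti_mirror"`,
#'   `"flat"`.
#' @param seed seed for the flat condition's eye choice.
#' @return a \linkS4class{StereoPair}; `meta` carries per-pixel hit
#'   masks, surface points and environment-lookup directions per eye
#'   for correspondence checks.
#' @export
renderCondition <- function(scene, condition = BINOCULAR_CONDITIONS,
                            seed = 1L) {
  condition <- match.arg(condition)
  eL <- c(-scene@iod / 2, 0, 0)
  eR <- c(scene@iod / 2, 0, 0)
  eC <- c(0, 0, 0)
  if (scene@viewDist <= scene@shape$baseRadius * (1 + scene@shape$amplitude))
    stop("mesh behind or enclosing the eyes: unfusable geometry")

  if (condition == "flat") {
    rng <- localRNG(deriveSeed(seed, 31))
    eye <- if (runif(1) < 0.5) "left" else "right"
    restoreRNG(rng)
    ePos <- if (eye == "left") eL else eR
    cast <- castRays(scene, ePos)
    V <- normalizeRows(sweep(cast$P, 2, ePos, function(p, e) e - p))
    omega <- reflectRay(V, cast$normals)
    vals <- envLookup(scene@env, omega)
    img <- layerToImage(vals, cast$hit & !is.na(omega[, 1]), cast$h, cast$w)
    meta <- list(flatEye = eye,
                 left = list(hit = matrix(cast$hit, cast$h, cast$w),
                             P = cast$P, normals = cast$normals,
                             omega = omega))
    meta$right <- meta$left
    return(new("StereoPair", left = img, right = img,
               condition = condition, meta = meta))
  }

  castL <- castRays(scene, eL)
  castR <- castRays(scene, eR)
  lookDir <- function(cast, eye) {
    V <- normalizeRows(sweep(cast$P, 2, eye, function(p, e) e - p))
    reflectRay(V, cast$normals)
  }
  omegaL <- switch(condition,
    mirror = lookDir(castL, eL),
    painted = lookDir(castL, eC),
    anti_mirror = lookDir(castL, eR))
  omegaR <- switch(condition,
    mirror = lookDir(castR, eR),
    painted = lookDir(castR, eC),
    anti_mirror = lookDir(castR, eL))
  left <- layerToImage(envLookup(scene@env, omegaL),
                       castL$hit & !is.na(omegaL[, 1]), castL$h, castL$w)
  right <- layerToImage(envLookup(scene@env, omegaR),
                        castR$hit & !is.na(omegaR[, 1]), castR$h, castR$w)
  new("StereoPair", left = left, right = right, condition = condition,
      meta = list(left = list(hit = matrix(castL$hit, castL$h, castL$w),
                              P = castL$P, normals = castL$normals,
                              omega = omegaL),
                  right = list(hit = matrix(castR$hit, castR$h, castR$w),
                               P = castR$P, normals = castR$normals,
                               omega = omegaR)))
}

# Bilinear rotation of one image layer about its centre; angle in
# degrees, normalized modulo 360 so full turns are exact identities.
rotateLayer <- function(layer, deg) {
  deg <- deg %% 360
  if (deg == 0) return(layer)
  h <- dim(layer)[1]; w <- dim(layer)[2]
  th <- -deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- rep(seq_len(h), w); gx <- rep(seq_len(w), each = h)
  # source coordinates: rotate backwards
  sx <- cos(th) * (gx - cx) - sin(th) * (gy - cy) + cx
  sy <- sin(th) * (gx - cx) + cos(th) * (gy - cy) + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- array(0, dim(layer))
  inb <- function(x, y) x >= 1 & x <= w & y >= 1 & y <= h
  for (c in seq_len(dim(layer)[3])) {
    ch <- layer[, , c]
    samp <- function(x, y) {
      v <- numeric(length(x))
      ok <- inb(x, y)
      v[ok] <- ch[cbind(y[ok], x[ok])]
      v
    }
    vals <- (1 - fx) * (1 - fy) * samp(x0, y0) +
            fx * (1 - fy) * samp(x0 + 1, y0) +
            (1 - fx) * fy * samp(x0, y0 + 1) +
            fx * fy * samp(x0 + 1, y0 + 1)
    out[, , c] <- matrix(vals, h, w)
  }
  out
}

#' Glossy/matte image pair by highlight rotation
#'
#' Renders the object once from the cyclopean viewpoint as two
#' separable layers: a Lambertian diffuse base (directional light plus
#' ambient) and a specular highlight layer (the environment reflection
#' raised to a power so it concentrates into highlights).  The glossy
#' image composites the specular layer in place; the matte image
#' composites it after rotating it by `rotationDeg` about the image
#' centre, masked to the object silhouette, which breaks the
#' congruence between highlights and shading that conveys gloss.
#'
#' @param scene a \linkS4class{Scene}.
#' @param rotationDeg in-plane highlight rotation, degrees (45 in the
#'   matte manipulation; 0 returns two identical images).
#' @param lightDir direction toward the light (diffuse shading).
#' @param ks,specPower specular layer gain and exponent.
#' @param albedo diffuse RGB albedo.
#' @return list with `glossy`, `matte` (h x w x 3 arrays sharing the
#'   identical silhouette), `silhouette`, and the two layers.
#' @export
makeMonocularPair <- function(scene, rotationDeg = 45,
                              lightDir = c(0.4, 0.6, -0.7),
                              ks = 0.9, specPower = 4,
                              albedo = c(0.45, 0.35, 0.30)) {
  eC <- c(0, 0, 0)
  cast <- castRays(scene, eC)
  hit <- cast$hit
  V <- normalizeRows(sweep(cast$P, 2, eC, function(p, e) e - p))
  omega <- reflectRay(V, cast$normals)
  l <- lightDir / sqrt(sum(lightDir^2))
  ndl <- pmax(as.numeric(cast$normals %*% l), 0)
  diffVals <- outer(0.25 + 0.75 * ndl, albedo)
  specVals <- ks * envLookup(scene@env, omega)^specPower
  specVals[is.na(specVals)] <- 0
  h <- cast$h; w <- cast$w
  diffuse <- layerToImage(diffVals, hit, h, w)
  spec <- layerToImage(specVals, hit, h, w, background = 0)
  sil <- matrix(hit, h, w)

  rotated <- rotateLayer(spec, rotationDeg)
  for (c in 1:3) rotated[, , c][!sil] <- 0
  if (sum(rotated) == 0 && sum(spec) > 0)
    warning("rotation moved the highlight layer entirely off the silhouette")
  clamp <- function(x) pmin(pmax(x, 0), 1)
  list(glossy = clamp(diffuse + spec), matte = clamp(diffuse + rotated),
       silhouette = sil, diffuse = diffuse, specular = spec,
       rotationDeg = rotationDeg)
}

#' Write a stereo pair as PNG files
#'
#' Writes `<prefix>_L.png` and `<prefix>_R.png`, plus an optional
#' side-by-side image for cross-fusing.
#'
#' @param pair a \linkS4class{StereoPair}.
#' @param dir output directory.
#' @param prefix file-name prefix (default: the condition).
#' @param sideBySide also write `<prefix>_LR.png`.
#' @return written paths, invisibly.
#' @export
writeStereoPair <- function(pair, dir, prefix = pair@condition,
                            sideBySide = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fl <- file.path(dir, paste0(prefix, "_L.png"))
  fr <- file.path(dir, paste0(prefix, "_R.png"))
  png::writePNG(pair@left, fl)
  png::writePNG(pair@right, fr)
  out <- c(fl, fr)
  if (sideBySide) {
    lr <- array(0, c(dim(pair@left)[1], 2 * dim(pair@left)[2], 3))
    lr[, seq_len(dim(pair@left)[2]), ] <- pair@left
    lr[, dim(pair@left)[2] + seq_len(dim(pair@left)[2]), ] <- pair@right
    flr <- file.path(dir, paste0(prefix, "_LR.png"))
    png::writePNG(lr, flr)
    out <- c(out, flr)
  }
  invisible(out)
}
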