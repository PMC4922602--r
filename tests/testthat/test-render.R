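test_that("reflection obeys the law of specular reflection", {
  # normal incidence reflects straight back
  n <- c(0, 0, 1)
  expect_equal(reflectRay(n, n), n)
  # 45-degree mirror symmetry
  V <- c(sin(pi / 4), 0, cos(pi / 4))
  expect_equal(reflectRay(V, n), c(-sin(pi / 4), 0, cos(pi / 4)))
  # property over random front-facing draws: unit length, coplanar,
  # equal angles to 1e-12
  set.seed(42)
  for (i in 1:1000) {
    nn <- rnorm(3); nn <- nn / sqrt(sum(nn^2))
    vv <- rnorm(3); vv <- vv / sqrt(sum(vv^2))
    if (sum(nn * vv) <= 1e-6) next
    om <- reflectRay(vv, nn)
    expect_equal(sum(om^2), 1, tolerance = 1e-12)
    expect_equal(acos(sum(om * nn)), acos(sum(vv * nn)), tolerance = 1e-12)
    expect_lt(abs(det(rbind(nn, vv, om))), 1e-12)  # coplanar
  }
  # back-facing samples are excluded
  expect_true(all(is.na(reflectRay(c(0, 0, -1), n))))
})

test_that("potato generation is seeded, star-shaped and validates amplitude", {
  s0 <- makePotato(seed = 1, amplitude = 0)
  r <- sqrt(rowSums(s0$vertices^2))
  expect_equal(r, rep(s0$baseRadius, length(r)))   # exact sphere
  s1a <- makePotato(seed = 1, amplitude = 0.2)
  s1b <- makePotato(seed = 1, amplitude = 0.2)
  expect_identical(s1a$vertices, s1b$vertices)     # bitwise determinism
  s2 <- makePotato(seed = 2, amplitude = 0.2)
  expect_gt(max(abs(s1a$vertices - s2$vertices)), 0)
  # distortion bounded by the amplitude
  r1 <- sqrt(rowSums(s1a$vertices^2))
  expect_true(all(r1 > s1a$baseRadius * 0.8 - 1e-9))
  expect_true(all(r1 < s1a$baseRadius * 1.2 + 1e-9))
  expect_error(makePotato(amplitude = 0.5), "amplitude")
  expect_error(makePotato(nModes = 0), "nModes")
})

test_that("potato mesh is closed (every edge shared by exactly two triangles)", {
  s <- makePotato(seed = 3, meshRes = 12)
  edges <- rbind(s$faces[, 1:2], s$faces[, 2:3], s$faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("flat condition duplicates one eye's image bitwise", {
  sc <- fixture("scene", function()
    makeScene(makePotato(seed = 1), makeEnvMap("blobs", seed = 2),
              imageSize = c(48L, 48L)))
  p <- renderCondition(sc, "flat", seed = 9)
  expect_identical(p@left, p@right)
  expect_true(p@meta$flatEye %in% c("left", "right"))
  # same seed -> identical render; the eye choice is seeded
  p2 <- renderCondition(sc, "flat", seed = 9)
  expect_identical(p@left, p2@left)
})

test_that("painted condition uses one cyclopean lookup direction per surface point", {
  sc <- fixture("scene", function()
    makeScene(makePotato(seed = 1), makeEnvMap("blobs", seed = 2),
              imageSize = c(48L, 48L)))
  p <- renderCondition(sc, "painted")
  # oracle: at each eye's own surface points, the stored lookup
  # direction must equal the cyclopean reflection recomputed from the
  # surface geometry alone -> identical across eyes at any common P
  for (eye in c("left", "right")) {
    m <- p@meta[[eye]]
    ok <- which(!is.na(m$omega[, 1]))
    ok <- ok[seq(1, length(ok), by = 17)]   # subsample for speed
    for (i in ok) {
      P <- m$P[i, ]
      n <- oracleNormal(sc@shape, P)
      Vc <- -P / sqrt(sum(P^2))             # cyclopean eye at the origin
      expect_equal(unname(m$omega[i, ]), unname(reflectRay(Vc, n)),
                   tolerance = 1e-5)
    }
  }
})

test_that("anti-mirror swaps the two eyes' reflected rays at each surface point", {
  sc <- fixture("scene", function()
    makeScene(makePotato(seed = 1), makeEnvMap("blobs", seed = 2),
              imageSize = c(48L, 48L)))
  anti <- renderCondition(sc, "anti_mirror")
  mir <- renderCondition(sc, "mirror")
  eR <- c(sc@iod / 2, 0, 0)
  # oracle: the anti-mirror left-eye lookup at P equals the mirror
  # right-eye reflection recomputed independently at the same P
  m <- anti@meta$left
  ok <- which(!is.na(m$omega[, 1]))
  ok <- ok[seq(1, length(ok), by = 17)]
  for (i in ok) {
    P <- m$P[i, ]
    n <- oracleNormal(sc@shape, P)
    VR <- (eR - P) / sqrt(sum((eR - P)^2))
    expect_equal(unname(m$omega[i, ]), unname(reflectRay(VR, n)),
                 tolerance = 1e-5)
  }
  # and the mirror right eye uses that same rule at its own points
  m2 <- mir@meta$right
  ok2 <- which(!is.na(m2$omega[, 1]))[c(10, 100, 400)]
  for (i in ok2) {
    P <- m2$P[i, ]
    n <- oracleNormal(sc@shape, P)
    VR <- (eR - P) / sqrt(sum((eR - P)^2))
    expect_equal(unname(m2$omega[i, ]), unname(reflectRay(VR, n)),
                 tolerance = 1e-5)
  }
})

test_that("rendering is deterministic and mirror eyes differ", {
  sc <- fixture("scene", function()
    makeScene(makePotato(seed = 1), makeEnvMap("blobs", seed = 2),
              imageSize = c(48L, 48L)))
  a <- renderCondition(sc, "mirror")
  b <- renderCondition(sc, "mirror")
  expect_identical(a@left, b@left)
  expect_identical(a@right, b@right)
  expect_false(identical(a@left, a@right))  # reflections carry disparity
  expect_true(all(a@left >= 0 & a@left <= 1))
})

test_that("highlight rotation produces matched glossy/matte pairs", {
  sc <- fixture("scene", function()
    makeScene(makePotato(seed = 1), makeEnvMap("blobs", seed = 2),
              imageSize = c(48L, 48L)))
  m0 <- makeMonocularPair(sc, rotationDeg = 0)
  expect_identical(m0$glossy, m0$matte)             # identity rotation
  m360 <- makeMonocularPair(sc, rotationDeg = 360)  # full turn
  expect_lt(max(abs(m360$glossy - m360$matte)), 1 / 255)
  m45 <- makeMonocularPair(sc, rotationDeg = 45)
  d <- abs(m45$glossy - m45$matte)
  outside <- !m45$silhouette
  for (c in 1:3) expect_equal(sum(d[, , c][outside]), 0)  # differ only inside
  expect_gt(sum(d), 0)
})

test_that("environment maps are seeded, bounded and wrap in longitude", {
  e1 <- makeEnvMap("blobs", seed = 4)
  expect_identical(e1, makeEnvMap("blobs", seed = 4))
  expect_true(all(e1 >= 0 & e1 <= 1))
  for (type in c("gradient", "checker"))
    expect_true(all(makeEnvMap(type, seed = 1) >= 0))
  # lookup is defined for every unit direction, including poles
  dirs <- rbind(c(0, 1, 0), c(0, -1, 0), c(1, 0, 0), c(-1, 0, 0))
  v <- glossMVPA:::envLookup(e1, dirs)
  expect_false(anyNA(v))
})

test_that("stereo pairs write PNG files", {
  sc <- fixture("scene", function()
    makeScene(makePotato(seed = 1), makeEnvMap("blobs", seed = 2),
              imageSize = c(48L, 48L)))
  p <- renderCondition(sc, "mirror")
  dir <- withr::local_tempdir()
  files <- writeStereoPair(p, dir, sideBySide = TRUE)
  expect_true(all(file.exists(files)))
  img <- png::readPNG(files[1])
  expect_equal(dim(img)[1:2], dim(p@left)[1:2])
})
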