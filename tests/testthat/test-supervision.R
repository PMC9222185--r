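straightPath <- function(row, col, n = 40) {
  ReferencePath(cbind(rep(row, n), rep(col, n)), zMin = 1L)
}

test_that("polar targets encode direction, capped radius and action", {
  path <- straightPath(50, 60)
  W <- 192
  tg <- polarTargets(c(50, 50), z = 5, path, W)
  expect_equal(tg$angleNorm, -1)            # atan2(0, +10) = 0
  expect_equal(tg$radiusNorm, 10 / W)
  expect_equal(tg$action, "move")
  # on-path centre
  tg2 <- polarTargets(c(50, 60), z = 5, path, W)
  expect_equal(tg2$radiusNorm, 0)
  expect_equal(tg2$action, "segment")
  expect_equal(tg2$angleNorm, -1)           # degenerate d = 0 convention
  # radius is limited to the width of the VOI
  tg3 <- polarTargets(c(50, 60 + 3 * W), z = 5, path, W)
  expect_equal(tg3$radiusNorm, 1)
  # above the path range
  tg4 <- polarTargets(c(50, 60), z = 41, path, W)
  expect_equal(tg4$action, "stop")
  # range invariants over random geometry
  set.seed(31)
  for (i in 1:200) {
    tg <- polarTargets(runif(2, -100, 200), z = 1, path, W = 32)
    expect_gte(tg$angleNorm, -1); expect_lt(tg$angleNorm, 1)
    expect_gte(tg$radiusNorm, 0); expect_lte(tg$radiusNorm, 1)
  }
})

test_that("applyPolarMove matches its closed-form examples", {
  expect_equal(applyPolarMove(c(50, 50), angleNorm = 0.3, radiusNorm = 0,
                              W = 32), c(50, 50))
  # angleNorm = -1 (theta = 0) moves purely along +col
  expect_equal(applyPolarMove(c(50, 50), -1, 10 / 32, 32), c(50, 60))
  # theta = pi/2 moves purely along +row
  expect_equal(applyPolarMove(c(50, 50), -0.5, 10 / 32, 32), c(60, 50))
})

test_that("the reference move inverts the targets (and contracts beyond W)", {
  path <- straightPath(25, 25, n = 10)
  W <- 16
  for (row in seq(1, 50, by = 1)) {
    for (col in seq(1, 50, by = 7)) {
      tg <- polarTargets(c(row, col), 3, path, W)
      newc <- applyPolarMove(c(row, col), tg$angleNorm, tg$radiusNorm, W)
      d0 <- sqrt(sum((c(row, col) - c(25, 25))^2))
      d1 <- sqrt(sum((newc - c(25, 25))^2))
      if (d0 <= W) {
        expect_lte(d1, sqrt(2) / 2 + 1e-9)   # lands on path within 1 voxel
      } else {
        expect_lte(abs((d0 - d1) - W), 1)    # contraction by exactly W
      }
    }
  }
})

test_that("training VOIs honour the positive fraction exactly", {
  cs <- defaultCase()
  vol <- voxels(clipNormalize(cs@ncct))
  msk <- voxels(cs@thrombus)
  set.seed(32)
  smp <- sampleTrainingVois(vol, msk, cs@path, n = 10,
                            positiveFraction = 0.4)
  nPos <- sum(vapply(smp$segs, function(s) any(s != 0), logical(1)))
  expect_gte(nPos, 4)
  # over many samples the fraction is exact by construction
  smp2 <- sampleTrainingVois(vol, msk, cs@path, n = 200,
                             positiveFraction = 0.4)
  frac <- mean(vapply(smp2$segs, function(s) any(s != 0), logical(1)))
  expect_gte(frac, 0.38); expect_lte(frac, 0.42)
  # fraction 0 works on a thrombus-free case; positives demanded -> error
  none <- array(0, dim(msk))
  expect_silent(sampleTrainingVois(vol, none, cs@path, 5,
                                   positiveFraction = 0))
  expect_error(sampleTrainingVois(vol, none, cs@path, 5,
                                  positiveFraction = 0.4, caseId = "c9"),
               "c9")
})

test_that("sampled VOIs carry consistent shapes, targets and coordinates", {
  cs <- defaultCase()
  set.seed(33)
  smp <- sampleTrainingVois(voxels(cs@ncct), voxels(cs@thrombus), cs@path,
                            n = 6, voiShape = c(32, 32, 8))
  expect_length(smp$vois, 6)
  expect_true(all(vapply(smp$vois, function(v)
    identical(dim(v), c(8L, 32L, 32L)), logical(1))))
  expect_true(all(smp$rel >= 0 & smp$rel <= 1))
  for (i in 1:6) {
    tg <- polarTargets(smp$centers[i, c("row", "col")], smp$centers[i, "z"],
                       cs@path, 32)
    expect_equal(smp$targets$angleNorm[i], tg$angleNorm)
    expect_equal(smp$targets$action[i], tg$action)
  }
})

test_that("identity augmentation is a no-op and translations shift the path", {
  cs <- generatePhantom(tinySpec(seed = 71))
  vol <- voxels(cs@ncct); msk <- voxels(cs@thrombus)
  idp <- polartrack:::identityAugmentParams()
  a <- augmentCase(vol, msk, cs@path, params = idp)
  expect_identical(a$vol, vol)
  expect_identical(a$mask, msk)
  expect_identical(a$path@points, cs@path@points)
  # pure translation
  tp <- polartrack:::identityAugmentParams(); tp$shift <- c(3, -5)
  b <- augmentCase(vol, msk, cs@path, params = tp)
  expect_equal(unname(b$path@points),
               unname(sweep(cs@path@points, 2, c(-3, 5))), tolerance = 1e-12)
  # image content also shifts: compare an interior probe
  expect_equal(b$vol[10, 30, 30], vol[10, 30 - 3, 30 + 5])
})

test_that("rotation shifts polar angles by the rotation angle", {
  d <- c(8L, 64L, 64L)
  set.seed(34)
  for (phi in c(-10, 4, 10)) {
    pr <- polartrack:::identityAugmentParams(); pr$rotDeg <- phi
    pts <- cbind(runif(5, 20, 44), runif(5, 20, 44))
    ctr <- cbind(runif(5, 20, 44), runif(5, 20, 44))
    newPts <- polartrack:::augmentMapPoint(pts, pr, d[2], d[3])
    newCtr <- polartrack:::augmentMapPoint(ctr, pr, d[2], d[3])
    for (i in 1:5) {
      th0 <- atan2(pts[i, 1] - ctr[i, 1], pts[i, 2] - ctr[i, 2])
      th1 <- atan2(newPts[i, 1] - newCtr[i, 1], newPts[i, 2] - newCtr[i, 2])
      dth <- (th1 - th0 - phi * pi / 180) %% (2 * pi)
      expect_lt(min(dth, 2 * pi - dth), 1e-9)
    }
  }
})

test_that("augment-then-recompute matches recompute-then-augment", {
  cs <- generatePhantom(tinySpec(seed = 72))
  W <- 32
  set.seed(35)
  params <- polartrack:::drawAugmentParams(maxShift = 8)
  a <- augmentCase(voxels(cs@ncct), voxels(cs@thrombus), cs@path,
                   params = params)
  d <- dim(voxels(cs@ncct))
  for (i in 1:20) {
    z <- sample(zRange(cs@path)[1]:zRange(cs@path)[2], 1)
    ctr <- c(runif(1, 16, d[2] - 16), runif(1, 16, d[3] - 16))
    # route 1: augment the centre, compute targets on the augmented path
    ctrA <- as.vector(polartrack:::augmentMapPoint(ctr, params, d[2], d[3]))
    tgA <- polarTargets(ctrA, z, a$path, W)
    # route 2: compute targets on the original path, transform the angle
    tg0 <- polarTargets(ctr, z, cs@path, W)
    flipSgn <- if (params$flip) -1 else 1
    th0 <- pi * (tg0$angleNorm + 1)
    thExp <- (flipSgn * th0 +
                (if (params$flip) pi else 0) +
                params$rotDeg * pi / 180) %% (2 * pi)
    thA <- pi * (tgA$angleNorm + 1)
    dth <- abs(thA - thExp) %% (2 * pi)
    dth <- min(dth, 2 * pi - dth)
    if (tg0$distance > 2) {          # angle unstable very close to the path
      expect_lt(dth, 2 * pi / 180 + 1e-6)
      expect_lt(abs(tgA$radiusNorm - min(tg0$distance * params$zoom, W) / W),
                2 / W)
    }
  }
})
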