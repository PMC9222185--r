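mkMask <- function(arr, sp = c(1, 1, 1)) SegmentationMask(arr, spacing = sp)

test_that("connected components respect the requested connectivity", {
  a <- array(0, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- 1
  expect_equal(nrow(connectedComponents(mkMask(a))$components), 1)
  # two voxels touching only across a diagonal
  b <- array(0, c(3, 3, 3)); b[1, 1, 1] <- 1; b[2, 2, 2] <- 1
  expect_equal(nrow(connectedComponents(mkMask(b), 26)$components), 1)
  expect_equal(nrow(connectedComponents(mkMask(b), 6)$components), 2)
  # edge-adjacency joins at 18 but not 6
  cc <- array(0, c(3, 3, 3)); cc[1, 1, 1] <- 1; cc[1, 2, 2] <- 1
  expect_equal(nrow(connectedComponents(mkMask(cc), 18)$components), 1)
  expect_equal(nrow(connectedComponents(mkMask(cc), 6)$components), 2)
})

test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(41)
  for (conn in c(6L, 18L, 26L)) {
    arr <- array(rbinom(12^3, 1, 0.25), c(12, 12, 12))
    mine <- connectedComponents(mkMask(arr), conn)
    orac <- floodLabel(arr, conn)
    expect_equal(max(mine$labels), max(orac))
    # identical partitions up to label permutation
    tab <- table(mine$labels[arr != 0], orac[arr != 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
  # checkerboard slice: 26-connectivity joins diagonals into one component
  chk <- array(0, c(1, 8, 8))
  chk[1, , ] <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(max(connectedComponents(mkMask(chk), 26)$labels),
               max(floodLabel(chk, 26)))
})

test_that("VBR removes components at the threshold and keeps larger ones", {
  sp <- c(1, 0.5, 0.5)
  d <- c(8, 40, 40)
  a <- array(0, d)
  a[1:4, 1:13, 1:5] <- 1          # 260 voxels = 0.065 mL (removed: not >)
  cut <- vbr(mkMask(a, sp))
  expect_equal(sum(voxels(cut)), 0)
  b <- array(0, d)
  b[1:4, 1:13, 11:15] <- 1
  b[5, 13, 11] <- 1               # 261 voxels (kept)
  expect_equal(sum(voxels(vbr(mkMask(b, sp)))), 261)
  # mixed mask: exactly the larger component remains
  expect_equal(sum(voxels(vbr(mkMask(pmin(a + b, 1), sp)))), 261)
  # empty in, empty out
  expect_equal(sum(voxels(vbr(mkMask(array(0, d), sp)))), 0)
})

test_that("VBR is monotone: it only ever deletes foreground", {
  set.seed(42)
  for (i in 1:20) {
    arr <- randomBlobMask(c(12, 12, 12))
    m <- mkMask(arr, c(1, 1, 1))
    out <- voxels(vbr(m, minVolumeMl = 0.02))
    expect_true(all(out <= arr))
  }
})

test_that("component matching applies the ten-percent rule literally", {
  d <- c(4, 10, 10)
  ref <- array(0, d); ref[, 1:5, 1:5] <- 1      # one 100-voxel component
  pred <- array(0, d); pred[, 6:10, 6:10] <- 1  # disjoint 100-voxel comp
  pred[1, 1, 1:10] <- 0
  # carve a predicted component overlapping ref by exactly 10 voxels
  pred2 <- array(0, d)
  pred2[1, 1:5, 1:5] <- 1                       # 25 voxels in ref
  pred2[1, 6:10, 1:5] <- 1                      # 25 outside
  pred2[2:3, 6:10, 1:5] <- 1                    # 50 outside -> 100 total
  m <- matchComponents(mkMask(ref), mkMask(pred2))
  expect_equal(m@tpPred, 1)                     # 25/100 >= 10%
  # 9 of 100 voxels overlapping -> FP
  pred3 <- array(0, d)
  pred3[1, 1:3, 1:3] <- 1                       # 9 voxels inside ref
  pred3[, 8:10, 8:10] <- 0
  pred3[1:4, 7:10, 7:10] <- 1                   # pad to ~73 outside
  sz <- sum(pred3)
  ov <- sum(pred3 * ref)
  expect_equal(ov, 9)
  m3 <- matchComponents(mkMask(ref), mkMask(pred3),
                        overlapFrac = 10 / sz + 1e-9)
  expect_equal(m3@fp, 1)
  # identical masks: everything matches
  m4 <- matchComponents(mkMask(ref), mkMask(ref))
  expect_equal(m4@tpRef, 1); expect_equal(m4@tpPred, 1)
  expect_equal(m4@fp, 0); expect_equal(m4@fn, 0)
  expect_error(matchComponents(mkMask(ref), mkMask(array(0, c(2, 2, 2)))),
               "shapes")
})

test_that("component matching equals the brute-force all-pairs oracle", {
  set.seed(43)
  for (i in 1:60) {
    refArr <- randomBlobMask()
    predArr <- randomBlobMask()
    m <- matchComponents(mkMask(refArr), mkMask(predArr))
    o <- bruteMatch(refArr, predArr)
    expect_equal(m@tpRef, o$tpRef)
    expect_equal(m@tpPred, o$tpPred)
    expect_equal(m@fp, o$fp)
    expect_equal(m@fn, o$fn)
  }
})

test_that("precision and recall follow the counting conventions", {
  d <- c(4, 12, 12)
  ref <- array(0, d); ref[, 1:3, 1:3] <- 1; ref[, 8:10, 8:10] <- 1
  pred <- ref
  pred[1:2, 5, 5] <- 1   # one extra unmatched blob
  m <- matchComponents(mkMask(ref), mkMask(pred))
  pr <- precisionRecall(m)
  expect_equal(unname(pr["precision"]), 2 / 3)
  expect_equal(unname(pr["recall"]), 1)
  # empty prediction vs nonempty reference
  m2 <- matchComponents(mkMask(ref), mkMask(array(0, d)))
  pr2 <- precisionRecall(m2)
  expect_equal(unname(pr2["precision"]), 0)
  expect_equal(unname(pr2["recall"]), 0)
  # no reference components: recall undefined
  m3 <- matchComponents(mkMask(array(0, d)), mkMask(pred))
  expect_true(is.na(precisionRecall(m3)["recall"]))
  # pooling equals recomputation from summed counts
  pooled <- precisionRecall(list(m, m2))
  expect_equal(unname(pooled["recall"]),
               (m@tpRef + m2@tpRef) / (m@tpRef + m2@tpRef + m@fn + m2@fn))
})

test_that("Dice matches hand-computed values and is symmetric", {
  d <- c(2, 4, 4)
  a <- array(0, d); a[1, 1:2, 1:4] <- 1          # 8 voxels
  b <- array(0, d); b[1, 2:3, 1:4] <- 1          # 8 voxels, 4 shared
  expect_equal(diceCoefficient(a, b), 0.5)
  expect_equal(diceCoefficient(b, a), 0.5)
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, array(0, d)), 0)
  expect_equal(diceCoefficient(array(0, d), array(0, d)), 1)
})

test_that("ICC(2,1) matches an independent ANOVA-based computation", {
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  res <- iccAgreement(x, y)
  # independent route: two-way ANOVA mean squares via stats::aov
  dat <- data.frame(score = c(x, y),
                    subj = factor(rep(1:6, 2)),
                    rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(score ~ subj + rater, data = dat))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  iccOracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(unname(res["icc"]), iccOracle, tolerance = 1e-6)
  expect_lt(res["ciLow"], res["icc"]); expect_gt(res["ciHigh"], res["icc"])
  # perfect agreement
  expect_equal(unname(iccAgreement(x, x)["icc"]), 1)
  expect_error(iccAgreement(1:3, 1:3), "at least 5")
})

test_that("ICC of pure noise is near zero across simulations", {
  set.seed(44)
  vals <- replicate(40, {
    x <- rnorm(30)
    iccAgreement(x, rnorm(30, sd = 4))["icc"]
  })
  expect_lt(abs(mean(vals)), 0.15)
})

test_that("Fisher r-to-z comparison matches closed forms", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  rz <- compareIccFisher(0.6, 50, 0.6, 80)
  expect_equal(unname(rz["z"]), 0)
  expect_equal(unname(rz["p"]), 1)
  rz2 <- compareIccFisher(0.41, 149, 0.38, 149)
  zExp <- (atanh(0.41) - atanh(0.38)) / sqrt(2 / 146)
  expect_equal(unname(rz2["z"]), zExp, tolerance = 1e-12)
  expect_gt(rz2["p"], 0.05)   # no significant volumetric-agreement difference
  expect_error(compareIccFisher(0.5, 3, 0.5, 10), "n > 3")
  expect_error(compareIccFisher(1, 10, 0.5, 10), "\\|r\\| < 1")
})

test_that("Bland-Altman bias and limits match closed forms", {
  expect_equal(unname(blandAltman(1:5, 1:5)), c(0, 0, 0))
  expect_equal(unname(blandAltman(c(2, 3, 4), c(1, 2, 3))), c(1, 1, 1))
  ba <- blandAltman(c(1, 3), c(1, 1))
  expect_equal(unname(ba),
               c(1, 1 - 1.96 * sqrt(2), 1 + 1.96 * sqrt(2)),
               tolerance = 1e-12)
  expect_error(blandAltman(1, 2), "at least 2")
})

test_that("Bland-Altman limits contain about 95% of normal differences", {
  set.seed(45)
  x <- rnorm(1e4); y <- x - rnorm(1e4, 0.3, 0.7)
  ba <- blandAltman(x, y)
  inside <- mean(x - y >= ba["loaLow"] & x - y <= ba["loaHigh"])
  expect_gt(inside, 0.94); expect_lt(inside, 0.96)
})

test_that("paired comparison gates on normality and adjusts p-values", {
  a <- c(1, 2, 3)
  expect_equal(pairedCompare(a, a)$pAdjusted, 1)
  set.seed(46)
  tBranch <- replicate(20, {
    x <- rnorm(30); y <- x + rnorm(30, mean = 1)
    r <- pairedCompare(y, x, nComparisons = 4)
    c(normal = r$normal, sig = r$pValue < 0.05, adjOk = r$pAdjusted >=
        r$pValue && r$pAdjusted <= 1)
  })
  expect_gt(mean(tBranch["normal", ]), 0.7)       # t-test branch dominates
  expect_gt(mean(tBranch["sig", ]), 0.9)
  expect_true(all(tBranch["adjOk", ] == 1))
  wBranch <- replicate(20, {
    x <- rnorm(40); y <- x + rcauchy(40)
    pairedCompare(y, x)$normal
  })
  expect_lt(mean(wBranch), 0.3)                   # heavy tails -> wilcoxon
})

test_that("cohort evaluation: oracle predictions give perfect scores", {
  set.seed(47)
  refs <- lapply(1:6, function(i) {
    arr <- array(0, c(6, 20, 20))
    arr[2:4, 3:(3 + i), 5:9] <- 1    # volumes differ across cases
    mkMask(arr, c(1, 0.5, 0.5))
  })
  rep <- evaluateCohort(refs, refs)
  expect_equal(rep$pooled$precision, 1)
  expect_equal(rep$pooled$recall, 1)
  expect_equal(rep$pooled$dice, 1)
  expect_equal(unname(rep$icc["icc"]), 1)
  expect_equal(unname(rep$blandAltman["bias"]), 0)
})

test_that("VBR restores precision lost to sub-threshold blobs", {
  set.seed(48)
  sp <- c(1, 0.5, 0.5)
  refs <- list(); preds <- list()
  for (i in 1:5) {
    arr <- array(0, c(8, 24, 24))
    arr[2:6, 5:(13 + i), 5:12] <- 1      # >= 0.09 mL, varying per case
    refs[[i]] <- mkMask(arr, sp)
    p <- arr
    p[8, 20:22, 20:22] <- 1              # 9-voxel blob, far below 0.065 mL
    preds[[i]] <- mkMask(p, sp)
  }
  noVbr <- evaluateCohort(refs, preds, applyVbr = FALSE)
  withVbr <- evaluateCohort(refs, preds, applyVbr = TRUE)
  expect_lt(noVbr$pooled$precision, 1)
  expect_equal(withVbr$pooled$precision, 1)
  expect_equal(withVbr$pooled$recall, noVbr$pooled$recall)
})

test_that("method variants compare with paired tests over shared cases", {
  set.seed(50)
  refs <- lapply(1:8, function(i) {
    arr <- array(0, c(6, 20, 20)); arr[2:4, 3:(4 + i), 5:9] <- 1
    mkMask(arr, c(1, 0.5, 0.5))
  })
  perfect <- evaluateCohort(refs, refs)
  # degrade one variant: drop one slice from each prediction
  worse <- lapply(refs, function(m) {
    v <- voxels(m); v[2, , ] <- 0
    mkMask(v, spacing(m))
  })
  degraded <- evaluateCohort(refs, worse)
  tab <- compareReports(perfect, degraded)
  expect_setequal(tab$metric, c("precision", "recall", "dice", "volPredMl"))
  expect_true(all(tab$pAdjusted >= tab$pValue | tab$pValue >= 1))
  # identical reports: every comparison degenerates to p = 1
  same <- compareReports(perfect, perfect)
  expect_true(all(same$pAdjusted == 1))
})

test_that("recall with VBR never exceeds recall without VBR", {
  set.seed(49)
  for (rep in 1:10) {
    refs <- lapply(1:4, function(i) mkMask(randomBlobMask(), c(1, 1, 1)))
    preds <- lapply(1:4, function(i) mkMask(randomBlobMask(), c(1, 1, 1)))
    a <- evaluateCohort(refs, preds, applyVbr = FALSE, minVolumeMl = 0.02)
    b <- evaluateCohort(refs, preds, applyVbr = TRUE, minVolumeMl = 0.02)
    if (!is.na(a$pooled$recall) && !is.na(b$pooled$recall))
      expect_lte(b$pooled$recall, a$pooled$recall)
    expect_lte(sum(b$perCase$fp), sum(a$perCase$fp))
  }
})
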