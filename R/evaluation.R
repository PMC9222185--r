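# Localization and volumetry evaluation: volume-based removal (VBR),
# connected-component matching with an overlap criterion, Dice, ICC(2,1)
# volume agreement, Bland-Altman limits of agreement, Fisher r-to-z
# comparison of ICCs, and Shapiro-Wilk-gated paired testing with
# Bonferroni correction.

#' Label connected components of a binary mask
#'
#' @param m a [SegmentationMask-class] (or 3D binary array).
#' @param connectivity voxel adjacency: 6, 18 or 26 (default: the most
#'   permissive, suited to thin elongated thrombi).
#' @return List: `labels` (integer array, 0 = background), `components`
#'   (data.frame with `label`, `voxels`, `volume_ml`).
#' @export
connectedComponents <- function(m, connectivity = 26) {
  arr <- if (is(m, "SegmentationMask")) voxels(m) else m
  sp <- if (is(m, "SegmentationMask")) spacing(m) else c(1, 1, 1)
  lab <- cclabel3(as.integer(arr != 0), dim(arr), as.integer(connectivity))
  k <- attr(lab, "n_components")
  labels <- array(as.integer(lab), dim(arr))
  sizes <- if (k > 0) tabulate(lab[lab > 0], nbins = k) else integer(0)
  list(labels = labels,
       components = data.frame(label = seq_len(k), voxels = sizes,
                               volume_ml = sizes * prod(sp) / 1000))
}

#' Volume-based removal of small components
#'
#' Deletes every connected component whose volume is less than or equal to
#' `minVolumeMl`; only strictly larger components survive.
#'
#' @param m a [SegmentationMask-class].
#' @param minVolumeMl volume threshold in mL.
#' @param connectivity component adjacency (6/18/26).
#' @return A [SegmentationMask-class] with small components removed.
#' @export
vbr <- function(m, minVolumeMl = 0.065, connectivity = 26) {
  cc <- connectedComponents(m, connectivity)
  keep <- cc$components$label[cc$components$volume_ml > minVolumeMl]
  arr <- array(as.numeric(cc$labels %in% keep & cc$labels > 0),
               dim(cc$labels))
  SegmentationMask(arr, spacing = spacing(m))
}

#' Match reference and predicted components by fractional overlap
#'
#' A predicted component counts as a true-positive localization when at
#' least `overlapFrac` of its voxels overlap some reference component;
#' otherwise it is a false positive. A reference component counts as
#' detected when at least `overlapFrac` of its voxels overlap some
#' predicted component; otherwise it is a false negative. With
#' `denominator = "min"`, the overlap fraction uses the smaller of the two
#' component sizes on both sides.
#'
#' @param ref,pred aligned [SegmentationMask-class] objects.
#' @param overlapFrac minimal overlap fraction (default 10 percent).
#' @param connectivity component adjacency.
#' @param denominator `"literal"` (per-side denominators) or `"min"`.
#' @return A [CCMatchResult-class].
#' @export
matchComponents <- function(ref, pred, overlapFrac = 0.10,
                            connectivity = 26,
                            denominator = c("literal", "min")) {
  denominator <- match.arg(denominator)
  refArr <- if (is(ref, "SegmentationMask")) voxels(ref) else ref
  predArr <- if (is(pred, "SegmentationMask")) voxels(pred) else pred
  if (!identical(dim(refArr), dim(predArr)))
    stop("matchComponents: mask shapes differ")
  ccR <- connectedComponents(ref, connectivity)
  ccP <- connectedComponents(pred, connectivity)
  nR <- nrow(ccR$components); nP <- nrow(ccP$components)
  O <- matrix(0, nR, nP)
  both <- ccR$labels > 0 & ccP$labels > 0
  if (any(both)) {
    tab <- table(ref = ccR$labels[both], pred = ccP$labels[both])
    O[cbind(as.integer(rownames(tab))[row(tab)],
            as.integer(colnames(tab))[col(tab)])] <- as.vector(tab)
  }
  refMatched <- logical(nR); predMatched <- logical(nP)
  if (nR > 0 && nP > 0) {
    szR <- ccR$components$voxels; szP <- ccP$components$voxels
    denR <- switch(denominator,
                   literal = matrix(szR, nR, nP),
                   min = outer(szR, szP, pmin))
    denP <- switch(denominator,
                   literal = matrix(szP, nR, nP, byrow = TRUE),
                   min = outer(szR, szP, pmin))
    refMatched <- apply(O / denR >= overlapFrac, 1, any)
    predMatched <- apply(O / denP >= overlapFrac, 2, any)
  }
  refDf <- cbind(ccR$components, matched = refMatched)
  predDf <- cbind(ccP$components, matched = predMatched)
  new("CCMatchResult", refComponents = refDf, predComponents = predDf,
      tpRef = sum(refMatched), tpPred = sum(predMatched),
      fp = sum(!predMatched), fn = sum(!refMatched))
}

#' Localization precision and recall from component matches
#'
#' `precision = tpPred / (tpPred + fp)` (0 by convention when there are no
#' predicted components) and `recall = tpRef / (tpRef + fn)` (`NA` when
#' there are no reference components). Accepts a single
#' [CCMatchResult-class] or a list of them, whose counts are pooled.
#'
#' @param r a [CCMatchResult-class], or list thereof.
#' @return Named numeric `c(precision, recall)`.
#' @export
precisionRecall <- function(r) {
  if (is(r, "CCMatchResult")) r <- list(r)
  tpPred <- sum(vapply(r, slot, integer(1), "tpPred"))
  fp <- sum(vapply(r, slot, integer(1), "fp"))
  tpRef <- sum(vapply(r, slot, integer(1), "tpRef"))
  fn <- sum(vapply(r, slot, integer(1), "fn"))
  c(precision = if (tpPred + fp == 0) 0 else tpPred / (tpPred + fp),
    recall = if (tpRef + fn == 0) NA_real_ else tpRef / (tpRef + fn))
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; 1 by convention when both masks are empty.
#' Cases without a visible reference thrombus should be excluded by the
#' caller before averaging Dice over a cohort.
#'
#' @param ref,pred aligned [SegmentationMask-class] objects (or arrays).
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(ref, pred) {
  a <- (if (is(ref, "SegmentationMask")) voxels(ref) else ref) != 0
  b <- (if (is(pred, "SegmentationMask")) voxels(pred) else pred) != 0
  if (!identical(dim(a), dim(b))) stop("diceCoefficient: shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Intra-class correlation for absolute agreement, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC of the
#' paired volumes, with the F-based 95 percent confidence interval.
#'
#' @param x,y paired measurement vectors (e.g. manual and automatic
#'   volumes, mL); at least 5 pairs.
#' @param conf confidence level.
#' @return Named numeric `c(icc, ciLow, ciHigh)`.
#' @export
iccAgreement <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("iccAgreement: unequal lengths")
  if (n < 5) stop("iccAgreement: need at least 5 pairs")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  rowM <- rowMeans(dat); colM <- colMeans(dat)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  if (!is.finite(lower)) lower <- NA_real_
  if (!is.finite(upper)) upper <- NA_real_
  c(icc = icc, ciLow = lower, ciHigh = upper)
}

#' Compare two correlation/ICC values by Fisher's r-to-z transformation
#'
#' @param r1,r2 coefficients, `|r| < 1`.
#' @param n1,n2 sample sizes, each > 3.
#' @return Named numeric `c(z, p)` (two-sided normal p-value).
#' @export
compareIccFisher <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("compareIccFisher: need n > 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("compareIccFisher: need |r| < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  c(z = z, p = 2 * pnorm(-abs(z)))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d = x - y`: bias is their mean, the limits of agreement
#' are `bias +/- 1.96 * sd(d)` (sample standard deviation).
#'
#' @param x,y paired vectors (at least 2 pairs).
#' @return Named numeric `c(bias, loaLow, loaHigh)`.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("blandAltman: unequal lengths")
  if (length(x) < 2) stop("blandAltman: need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  c(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s)
}

#' Paired comparison with a normality-gated test and Bonferroni correction
#'
#' Shapiro-Wilk on the paired differences (at `alpha`) selects a paired
#' t-test (normal) or the paired nonparametric alternative (Wilcoxon
#' signed-rank by default; the two-sample rank-sum form is available
#' behind a flag). The p-value is multiplied by `nComparisons` and capped
#' at 1.
#'
#' @param a,b paired metric vectors.
#' @param alpha normality-test level.
#' @param nComparisons Bonferroni family size.
#' @param nonparametric `"signed-rank"` (paired) or `"rank-sum"`.
#' @return List: `test`, `statistic`, `pValue`, `pAdjusted`, `shapiroP`,
#'   `normal`.
#' @export
pairedCompare <- function(a, b, alpha = 0.05, nComparisons = 1,
                          nonparametric = c("signed-rank", "rank-sum")) {
  nonparametric <- match.arg(nonparametric)
  if (length(a) != length(b)) stop("pairedCompare: unequal lengths")
  d <- a - b
  if (all(d == 0))
    return(list(test = "degenerate", statistic = NA_real_, pValue = 1,
                pAdjusted = 1, shapiroP = NA_real_, normal = NA))
  if (sd(d) == 0) {
    # constant nonzero shift: normality is undefined, the t-test is
    # degenerate; the signed-rank branch handles it
    swP <- NA_real_
    normal <- FALSE
  } else {
    sw <- shapiro.test(d)
    swP <- sw$p.value
    normal <- swP > alpha
  }
  if (normal) {
    tt <- t.test(a, b, paired = TRUE)
    test <- "paired t"; statp <- unname(tt$statistic); p <- tt$p.value
  } else if (nonparametric == "signed-rank") {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
    test <- "wilcoxon signed-rank"; statp <- unname(wt$statistic)
    p <- wt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    test <- "wilcoxon rank-sum"; statp <- unname(wt$statistic)
    p <- wt$p.value
  }
  list(test = test, statistic = statp, pValue = p,
       pAdjusted = min(1, p * nComparisons), shapiroP = swP,
       normal = normal)
}

#' Evaluate a cohort of reference/predicted segmentations
#'
#' Per-case localization precision/recall (component matching at the
#' overlap criterion), Dice (cases with an empty reference excluded from
#' the Dice aggregate), and volume agreement (ICC(2,1), Bland-Altman).
#' Aggregate precision/recall are pooled over component counts across the
#' cohort; per-case means are reported alongside. Optionally applies VBR
#' to the predictions first.
#'
#' @param refs,preds lists of aligned [SegmentationMask-class] objects.
#' @param categories optional per-case location labels for stratified
#'   aggregates.
#' @param applyVbr apply [vbr()] to each prediction first.
#' @param minVolumeMl VBR threshold (mL).
#' @param overlapFrac localization overlap criterion.
#' @param connectivity component adjacency.
#' @return List of class `"EvalReport"`: `perCase` (data.frame), `pooled`,
#'   `perCaseMeans`, `perCategory`, `icc`, `blandAltman`, `settings`.
#' @export
evaluateCohort <- function(refs, preds, categories = NULL, applyVbr = FALSE,
                           minVolumeMl = 0.065, overlapFrac = 0.10,
                           connectivity = 26) {
  n <- length(refs)
  stopifnot(length(preds) == n)
  if (is.null(categories)) categories <- rep("all", n)
  if (applyVbr) preds <- lapply(preds, vbr, minVolumeMl = minVolumeMl,
                                connectivity = connectivity)
  matches <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- matchComponents(refs[[i]], preds[[i]], overlapFrac, connectivity)
    matches[[i]] <- m
    pr <- precisionRecall(m)
    refEmpty <- sum(voxels(refs[[i]]) != 0) == 0
    rows[[i]] <- data.frame(
      case = i, category = categories[i],
      tpRef = m@tpRef, tpPred = m@tpPred, fp = m@fp, fn = m@fn,
      precision = pr["precision"], recall = pr["recall"],
      dice = if (refEmpty) NA_real_ else
        diceCoefficient(refs[[i]], preds[[i]]),
      volRefMl = volumeMl(refs[[i]]), volPredMl = volumeMl(preds[[i]]),
      refEmpty = refEmpty, row.names = NULL)
  }
  perCase <- do.call(rbind, rows)
  pooledPr <- precisionRecall(matches)
  pooled <- list(precision = unname(pooledPr["precision"]),
                 recall = unname(pooledPr["recall"]),
                 dice = mean(perCase$dice, na.rm = TRUE))
  perCaseMeans <- list(precision = mean(perCase$precision, na.rm = TRUE),
                       recall = mean(perCase$recall, na.rm = TRUE),
                       dice = mean(perCase$dice, na.rm = TRUE))
  perCategory <- do.call(rbind, lapply(unique(categories), function(cat) {
    idx <- which(categories == cat)
    pr <- precisionRecall(matches[idx])
    data.frame(category = cat, n = length(idx),
               precision = unname(pr["precision"]),
               recall = unname(pr["recall"]),
               dice = mean(perCase$dice[idx], na.rm = TRUE))
  }))
  icc <- tryCatch(iccAgreement(perCase$volRefMl, perCase$volPredMl),
                  error = function(e) c(icc = NA_real_, ciLow = NA_real_,
                                        ciHigh = NA_real_))
  ba <- tryCatch(blandAltman(perCase$volRefMl, perCase$volPredMl),
                 error = function(e) c(bias = NA_real_, loaLow = NA_real_,
                                       loaHigh = NA_real_))
  structure(list(perCase = perCase, pooled = pooled,
                 perCaseMeans = perCaseMeans, perCategory = perCategory,
                 icc = icc, blandAltman = ba,
                 settings = list(applyVbr = applyVbr,
                                 minVolumeMl = minVolumeMl,
                                 overlapFrac = overlapFrac,
                                 connectivity = connectivity)),
            class = "EvalReport")
}

#' Pairwise comparison of two method variants
#'
#' Compares the per-case metrics of two [evaluateCohort()] reports over
#' the same cohort (e.g. with and without VBR, or tracking versus grid)
#' with [pairedCompare()], one test per metric, Bonferroni-adjusted for
#' the number of metrics tested.
#'
#' @param a,b `"EvalReport"` objects over the same cases.
#' @param metrics per-case columns to compare.
#' @return data.frame: metric, test, statistic, pValue, pAdjusted.
#' @export
compareReports <- function(a, b, metrics = c("precision", "recall", "dice",
                                             "volPredMl")) {
  stopifnot(inherits(a, "EvalReport"), inherits(b, "EvalReport"),
            nrow(a$perCase) == nrow(b$perCase))
  rows <- lapply(metrics, function(m) {
    x <- a$perCase[[m]]; y <- b$perCase[[m]]
    ok <- is.finite(x) & is.finite(y)
    r <- pairedCompare(x[ok], y[ok], nComparisons = length(metrics))
    data.frame(metric = m, test = r$test, statistic = r$statistic,
               pValue = r$pValue, pAdjusted = r$pAdjusted)
  })
  do.call(rbind, rows)
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport (%d cases%s)\n", nrow(x$perCase),
              if (x$settings$applyVbr) ", VBR applied" else ""))
  cat(sprintf("  pooled precision %.3f, recall %.3f, mean Dice %.3f\n",
              x$pooled$precision, x$pooled$recall, x$pooled$dice))
  cat(sprintf("  volume ICC(2,1) %.3f [%.3f, %.3f]; bias %.3f mL, LoA [%.3f, %.3f]\n",
              x$icc["icc"], x$icc["ciLow"], x$icc["ciHigh"],
              x$blandAltman["bias"], x$blandAltman["loaLow"],
              x$blandAltman["loaHigh"]))
  invisible(x)
}
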