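# Losses, cyclical learning-rate schedule, the two training loops
# (backbone segmentation, then frozen-backbone polar heads) and stratified
# cross-validation folds.

#' Focal loss
#'
#' Mean over elements of `-alpha_t * (1 - p_t)^gamma * log(p_t)` with
#' `p_t = p` where `y = 1` and `1 - p` where `y = 0`, and `alpha_t = alpha`
#' for positives, `1 - alpha` for negatives. Probabilities are clamped to
#' `[eps, 1 - eps]`, so the loss is never NaN.
#'
#' @param p probabilities (any numeric array).
#' @param y binary labels, same shape.
#' @param alpha positive-class weight.
#' @param gamma focusing exponent (>= 0); `gamma = 0` reduces to
#'   alpha-weighted cross-entropy.
#' @param eps clamping epsilon.
#' @return Scalar loss.
#' @export
focalLoss <- function(p, y, alpha = 0.25, gamma = 2, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- y * p + (1 - y) * (1 - p)
  at <- y * alpha + (1 - y) * (1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

# d(focalLoss)/dp, same shape as p (mean reduction included).
focalLossGrad <- function(p, y, alpha = 0.25, gamma = 2, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- y * p + (1 - y) * (1 - p)
  at <- y * alpha + (1 - y) * (1 - alpha)
  dpt <- at * (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt)
  dpt * (2 * y - 1) / length(p)
}

#' Mean squared error
#' @param pred,target numeric vectors/arrays of equal shape.
#' @return Scalar mean of squared differences.
#' @export
l2Loss <- function(pred, target) mean((pred - target)^2)

#' Cyclical (triangular) learning rate
#'
#' Linearly increases from `lrMin` to `lrMax` over `rampIters` iterations,
#' then back down over the next `rampIters`, periodically.
#'
#' @param it iteration index (0-based).
#' @param lrMin,lrMax learning-rate bounds.
#' @param rampIters iterations per ramp (half period).
#' @return Learning rate at iteration `it`.
#' @export
cyclicalLr <- function(it, lrMin = 2e-5, lrMax = 1e-3, rampIters = 300) {
  phase <- it %% (2 * rampIters)
  if (phase <= rampIters) lrMin + (lrMax - lrMin) * phase / rampIters
  else lrMax - (lrMax - lrMin) * (phase - rampIters) / rampIters
}

#' Training configuration
#'
#' Defaults are the full-scale recipe; [deskTrainConfig()] is the small
#' profile used for CPU-scale runs.
#'
#' @param batchBl,batchPolar batch sizes of the two stages.
#' @param epochsBl,epochsPolar epoch counts.
#' @param itersPerEpoch iterations per epoch.
#' @param lrMax,lrMin,rampIters cyclical learning-rate parameters.
#' @param weightDecayBl,weightDecayPolar Adam L2 weight decay per stage.
#' @param focalAlpha,focalGamma focal-loss parameters.
#' @param positiveFraction fraction of sampled VOIs containing thrombus.
#' @param augment apply geometric augmentation during training.
#' @param maxShift maximal augmentation translation (voxels).
#' @param tol on-path action tolerance (voxels).
#' @return List of class `"TrainConfig"`.
#' @export
trainConfig <- function(batchBl = 32L, batchPolar = 128L, epochsBl = 300L,
                        epochsPolar = 100L, itersPerEpoch = 148L,
                        lrMax = 1e-3, lrMin = 2e-5, rampIters = 300L,
                        weightDecayBl = 2e-6, weightDecayPolar = 2e-5,
                        focalAlpha = 0.25, focalGamma = 2,
                        positiveFraction = 0.4, augment = TRUE,
                        maxShift = 80, tol = 8) {
  if (lrMin >= lrMax) stop("trainConfig: need lrMin < lrMax")
  structure(as.list(environment()), class = "TrainConfig")
}

#' Desk-scale training configuration
#'
#' Same code paths as the full recipe at a size that trains in minutes on
#' one CPU: 15 x 20 iterations (batch 4) for the backbone and 8 x 20
#' (batch 8) for the polar heads, a 50-iteration learning-rate ramp (one
#' full cycle per 100 iterations) and a 10-voxel augmentation shift
#' matched to the phantom field of view.
#' @return A `"TrainConfig"`.
#' @export
deskTrainConfig <- function() {
  trainConfig(batchBl = 4L, batchPolar = 8L, epochsBl = 15L,
              epochsPolar = 8L, itersPerEpoch = 20L, rampIters = 50L,
              maxShift = 10)
}

# Internal: normalize a list of PhantomCase / list(vol, mask, path) into
# plain training cases with preprocessed arrays.
prepareTrainingCases <- function(cases) {
  lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    if (is(cs, "PhantomCase")) {
      list(vol = voxels(clipNormalize(cs@ncct)), mask = voxels(cs@thrombus),
           path = cs@path, id = paste0("case", i))
    } else {
      list(vol = if (is(cs$vol, "ImageVolume")) voxels(cs$vol) else cs$vol,
           mask = if (is(cs$mask, "SegmentationMask")) voxels(cs$mask)
                  else cs$mask,
           path = cs$path, id = if (is.null(cs$id)) paste0("case", i)
                                else cs$id)
    }
  })
}

batchToTensors <- function(vois, segs) {
  list(x = arrayToTensor(vois),
       y = matrix(unlist(segs, use.names = FALSE), nrow = 1))
}

#' Train the BL-UNet backbone
#'
#' Randomly initialized; trained on sampled VOIs (a fixed fraction
#' containing thrombus) with the focal segmentation loss, Adam, and the
#' cyclical learning rate. Augmentation (when enabled) resamples each
#' case once per epoch on first use.
#'
#' @param cases list of [PhantomCase-class] (or lists with `vol`, `mask`,
#'   `path`); volumes are clip-normalized internally when given as
#'   phantoms.
#' @param netCfg a [netConfig()].
#' @param cfg a [trainConfig()].
#' @param seed integer seed (weights, sampling, augmentation).
#' @return List: `net` (a `"BlUnet"`), `log` (per-epoch data.frame),
#'   `sampledCases` (iteration-wise case indices, for reproducibility
#'   checks).
#' @export
trainBl <- function(cases, netCfg = deskNetConfig(), cfg = deskTrainConfig(),
                    seed = 1L) {
  prep <- prepareTrainingCases(cases)
  hasFg <- vapply(prep, function(cs) any(cs$mask != 0), logical(1))
  if (cfg$positiveFraction > 0 && !any(hasFg))
    stop("trainBl: no case contains a thrombus")
  net <- buildBlUnet(netCfg, seed = seed)
  st <- adamInit()
  voiShape <- c(netCfg$W, netCfg$W, netCfg$D)
  withSeed(seed + 1L, {
    it <- 0L
    logRows <- list()
    sampledCases <- integer(0)
    for (epoch in seq_len(cfg$epochsBl)) {
      augCache <- vector("list", length(prep))
      losses <- numeric(cfg$itersPerEpoch)
      for (iter in seq_len(cfg$itersPerEpoch)) {
        ci <- sample.int(length(prep), 1L)
        sampledCases <- c(sampledCases, ci)
        cs <- prep[[ci]]
        if (cfg$augment) {
          if (is.null(augCache[[ci]])) {
            a <- augmentCase(cs$vol, cs$mask, cs$path,
                             maxShift = cfg$maxShift)
            augCache[[ci]] <- list(vol = a$vol, mask = a$mask, path = a$path,
                                   id = cs$id)
          }
          cs <- augCache[[ci]]
        }
        posFrac <- if (any(cs$mask != 0)) cfg$positiveFraction else 0
        smp <- sampleTrainingVois(cs$vol, cs$mask, cs$path, cfg$batchBl,
                                  posFrac, voiShape,
                                  tol = cfg$tol, caseId = cs$id)
        bt <- batchToTensors(smp$vois, smp$segs)
        cache <- new.env(parent = emptyenv())
        out <- blFwd(net, bt$x, cache = cache)
        p <- out$probs$x
        loss <- focalLoss(p, bt$y, cfg$focalAlpha, cfg$focalGamma)
        if (!is.finite(loss))
          stop("trainBl: loss diverged (NaN/Inf) at epoch ", epoch,
               ", iteration ", iter)
        losses[iter] <- loss
        dp <- focalLossGrad(p, bt$y, cfg$focalAlpha, cfg$focalGamma)
        dLogits <- nnTensor(dp * p * (1 - p), out$probs$sp, out$probs$n)
        G <- newGradEnv()
        blBwd(net, G, cache, dLogits)
        adamStep(net$P, G, st, ls(net$P), cyclicalLr(it, cfg$lrMin,
                                                     cfg$lrMax,
                                                     cfg$rampIters),
                 cfg$weightDecayBl)
        it <- it + 1L
      }
      logRows[[epoch]] <- data.frame(epoch = epoch,
                                     meanLoss = mean(losses))
    }
    list(net = net, log = do.call(rbind, logRows),
         sampledCases = sampledCases)
  })
}

actionToOneHot <- function(action) {
  m <- matrix(0, 3, length(action))
  m[cbind(match(action, POLAR_ACTIONS), seq_along(action))] <- 1
  m
}

#' Train the Polar-UNet heads on a frozen backbone
#'
#' The backbone (down path, up path, segmentation head) keeps the
#' pre-trained weights and is not updated; only the added head layers
#' (with batch normalization) train, with focal loss for the action
#' classification, L2 for angle and radius, and the focal segmentation
#' loss computed for the log (it has no trainable upstream parameters).
#'
#' @param backbone a trained `"BlUnet"` (or a checkpoint path).
#' @param cases training cases as in [trainBl()].
#' @param netCfg,cfg,seed as in [trainBl()].
#' @return List: `net` (a `"PolarUnet"`), `log` (per-epoch loss terms).
#' @export
trainPolar <- function(backbone, cases, netCfg = NULL,
                       cfg = deskTrainConfig(), seed = 1L) {
  if (is.character(backbone)) backbone <- loadCheckpoint(backbone)
  netCfg <- backbone$cfg
  prep <- prepareTrainingCases(cases)
  net <- buildPolarUnet(backbone, seed = seed)
  st <- adamInit()
  voiShape <- c(netCfg$W, netCfg$W, netCfg$D)
  withSeed(seed + 2L, {
    it <- 0L
    logRows <- list()
    for (epoch in seq_len(cfg$epochsPolar)) {
      augCache <- vector("list", length(prep))
      terms <- matrix(0, cfg$itersPerEpoch, 4,
                      dimnames = list(NULL, c("seg", "action", "angle",
                                              "radius")))
      for (iter in seq_len(cfg$itersPerEpoch)) {
        ci <- sample.int(length(prep), 1L)
        cs <- prep[[ci]]
        if (cfg$augment) {
          if (is.null(augCache[[ci]])) {
            a <- augmentCase(cs$vol, cs$mask, cs$path,
                             maxShift = cfg$maxShift)
            augCache[[ci]] <- list(vol = a$vol, mask = a$mask, path = a$path,
                                   id = cs$id)
          }
          cs <- augCache[[ci]]
        }
        posFrac <- if (any(cs$mask != 0)) cfg$positiveFraction else 0
        smp <- sampleTrainingVois(cs$vol, cs$mask, cs$path, cfg$batchPolar,
                                  posFrac, voiShape, tol = cfg$tol,
                                  caseId = cs$id)
        bt <- batchToTensors(smp$vois, smp$segs)
        cache <- new.env(parent = emptyenv())
        # the segmentation term has no trainable upstream parameters (the
        # decoder is frozen); it is evaluated once per epoch for the log
        wantSeg <- iter == cfg$itersPerEpoch
        out <- polarFwd(net, bt$x, smp$rel, cache = cache, train = TRUE,
                        wantSeg = wantSeg)
        aOne <- actionToOneHot(smp$targets$action)
        segL <- if (wantSeg) focalLoss(out$segProbs$x, bt$y, cfg$focalAlpha,
                                       cfg$focalGamma) else NA_real_
        pAct <- out$actionProbs
        ptAct <- colSums(pAct * aOne)
        actL <- focalLoss(ptAct, rep(1, length(ptAct)), cfg$focalAlpha,
                          cfg$focalGamma)
        angL <- l2Loss(out$angle, smp$targets$angleNorm)
        radL <- l2Loss(out$radius, smp$targets$radiusNorm)
        total <- actL + angL + radL + if (wantSeg) segL else 0
        if (!is.finite(total))
          stop("trainPolar: loss diverged at epoch ", epoch, ", iteration ",
               iter)
        terms[iter, ] <- c(if (wantSeg) segL else NA_real_, actL, angL,
                           radL)
        n <- length(ptAct)
        # focal grad on the true-class softmax probability
        eps <- 1e-7
        ptc <- pmin(pmax(ptAct, eps), 1 - eps)
        g <- cfg$focalAlpha *
          (cfg$focalGamma * (1 - ptc)^(cfg$focalGamma - 1) * log(ptc) -
             (1 - ptc)^cfg$focalGamma / ptc) / n
        dzc <- sweep(aOne - pAct, 2, ptAct * g, "*")
        dAng <- 2 * (out$angle - smp$targets$angleNorm) / n
        dza <- dAng * (1 - out$angle^2)
        dRad <- 2 * (out$radius - smp$targets$radiusNorm) / n
        dzr <- dRad * out$radius * (1 - out$radius)
        G <- newGradEnv()
        polarBwd(net, G, cache, dza, dzr, dzc)
        adamStep(net$P, G, st, net$trainable,
                 cyclicalLr(it, cfg$lrMin, cfg$lrMax, cfg$rampIters),
                 cfg$weightDecayPolar)
        it <- it + 1L
      }
      logRows[[epoch]] <- data.frame(epoch = epoch,
                                     seg = mean(terms[, "seg"],
                                                na.rm = TRUE),
                                     action = mean(terms[, "action"]),
                                     angle = mean(terms[, "angle"]),
                                     radius = mean(terms[, "radius"]))
    }
    list(net = net, log = do.call(rbind, logRows))
  })
}

#' Stratified k-fold assignment with a held-out hyper-parameter fold
#'
#' Cases are stratified by the given category labels; fold 1 is flagged as
#' the hyper-parameter fold and excluded from aggregate evaluation. A
#' stratum smaller than `k` falls back to global round-robin assignment
#' with a warning.
#'
#' @param categories per-case stratum labels.
#' @param k number of folds.
#' @param seed shuffling seed.
#' @return List: `fold` (integer per case), `excludedFold` (1), `evalFolds`
#'   (folds used for evaluation).
#' @export
makeFolds <- function(categories, k = 5L, seed = 1L) {
  n <- length(categories)
  if (k > n) stop("makeFolds: k exceeds the number of cases")
  fold <- integer(n)
  withSeed(seed, {
    small <- names(which(table(categories) < k))
    if (length(small))
      warning("makeFolds: strata smaller than k assigned globally: ",
              paste(small, collapse = ", "))
    counts <- integer(k)   # global fill order for balance
    for (cat in unique(categories)) {
      idx <- which(categories == cat)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        f <- which.min(counts)
        fold[i] <- f
        counts[f] <- counts[f] + 1L
      }
    }
  })
  list(fold = fold, excludedFold = 1L, evalFolds = setdiff(seq_len(k), 1L))
}
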