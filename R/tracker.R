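# Inference: the Polar-UNet moving-VOI state machine and the BL-UNet
# non-overlapping grid.

#' Track the brainstem and segment with a moving VOI
#'
#' The VOI starts at the centre of the most caudal axial slice. At every
#' step the network is forwarded on the current VOI; if the predicted
#' action is "move" and fewer than `maxMoves` in-slice moves have been
#' spent, the predicted polar move is applied (a move whose VOI would
#' leave the in-plane volume bounds instead ascends one slice and resets
#' the centre). On "segment" (or when the move budget is exhausted) the
#' VOI's segmentation probabilities are written into the output volume
#' (overlaps combine by voxelwise maximum) and the VOI ascends. "stop"
#' (or passing the top slice) terminates.
#'
#' @param vol preprocessed [ImageVolume-class] (or 3D array).
#' @param net a `"PolarUnet"` or a function `f(voi, rel)` returning
#'   `list(angle, radius, actionProbs, segProbs)`.
#' @param voiShape `(W, W, D)`; defaults to the network configuration.
#' @param maxMoves in-slice move budget.
#' @param probThreshold binarization threshold on probabilities.
#' @return List: `mask` ([SegmentationMask-class]), `trajectory`
#'   (data.frame step/z/row/col/action/movesInSlice), `forwards` (number
#'   of network forward passes), `probs` (probability array).
#' @export
trackAndSegment <- function(vol, net, voiShape = NULL, maxMoves = 10,
                            probThreshold = 0.5) {
  sp <- if (is(vol, "ImageVolume")) spacing(vol) else c(1, 1, 1)
  arr <- if (is(vol, "ImageVolume")) voxels(vol) else vol
  if (is.null(voiShape)) {
    if (is.function(net))
      stop("trackAndSegment: voiShape is required for a function network")
    voiShape <- c(net$cfg$W, net$cfg$W, net$cfg$D)
  }
  W <- voiShape[1]; D <- voiShape[3]
  d <- dim(arr)
  # staged forward for network objects: the decoder only runs on steps
  # that actually segment (a "move" step needs just the down path + heads)
  stepper <- if (is.function(net)) {
    function(voi, rel) {
      out <- net(voi, rel)
      out$segBlock <- function() out$segProbs
      out
    }
  } else {
    function(voi, rel) {
      tin <- arrayToTensor(voi)
      feats <- blFwdDown(net, tin)
      out <- polarHeadsFwd(net, feats, matrix(rel, 3, 1))
      out$actionProbs <- as.vector(out$actionProbs)
      out$segBlock <- function()
        tensorToArrays(blFwdUp(net, feats)$probs)[[1]]
      out
    }
  }
  probs <- array(0, d)
  center <- c((d[2] + 1) / 2, (d[3] + 1) / 2)
  z <- 1L
  moves <- 0L
  forwards <- 0L
  traj <- list()
  while (z <= d[1]) {
    voi <- voiCrop(arr, z, center[1], center[2], D, W)
    rel <- pmin(pmax(c(z / d[1], center[1] / d[2], center[2] / d[3]), 0), 1)
    out <- stepper(voi, rel)
    forwards <- forwards + 1L
    act <- which.max(out$actionProbs)   # ties resolve to "move"
    traj[[length(traj) + 1L]] <-
      data.frame(step = forwards, z = z, row = center[1], col = center[2],
                 action = POLAR_ACTIONS[act], movesInSlice = moves)
    if (act == 3L) break
    if (act == 1L && moves < maxMoves) {
      newc <- applyPolarMove(center, out$angle, out$radius, W)
      if (!voiInBounds(newc, d[2], d[3], W)) {
        z <- z + 1L
        center <- c((d[2] + 1) / 2, (d[3] + 1) / 2)
        moves <- 0L
      } else {
        center <- newc
        moves <- moves + 1L
      }
    } else {
      probs <- voiPasteMax(probs, out$segBlock(), z, center[1], center[2])
      z <- z + 1L
      moves <- 0L
    }
  }
  mask <- SegmentationMask(array(as.numeric(probs >= probThreshold), d),
                           spacing = sp)
  list(mask = mask, trajectory = do.call(rbind, traj), forwards = forwards,
       probs = probs)
}

#' Segment a full volume with a non-overlapping VOI grid
#'
#' Tiles the volume with non-overlapping VOIs (the remainder is
#' zero-padded), forwards each tile, stitches the probabilities (each
#' voxel is written exactly once) and thresholds.
#'
#' @param vol preprocessed [ImageVolume-class] (or 3D array).
#' @param net a `"BlUnet"` (or `"PolarUnet"`, whose backbone is used).
#' @param voiShape `(W, W, D)`; defaults to the network configuration.
#' @param probThreshold binarization threshold.
#' @return List: `mask` ([SegmentationMask-class]), `probs` (probability
#'   array), `forwards` (number of tiles forwarded).
#' @export
gridSegment <- function(vol, net, voiShape = NULL, probThreshold = 0.5) {
  sp <- if (is(vol, "ImageVolume")) spacing(vol) else c(1, 1, 1)
  arr <- if (is(vol, "ImageVolume")) voxels(vol) else vol
  if (is.null(voiShape)) voiShape <- c(net$cfg$W, net$cfg$W, net$cfg$D)
  W <- voiShape[1]; D <- voiShape[3]
  d <- dim(arr)
  probs <- array(0, d)
  forwards <- 0L
  for (zlo in seq(1L, d[1], by = D)) {
    for (rlo in seq(1L, d[2], by = W)) {
      for (clo in seq(1L, d[3], by = W)) {
        tile <- array(0, c(D, W, W))
        zs <- zlo:min(d[1], zlo + D - 1L)
        rs <- rlo:min(d[2], rlo + W - 1L)
        cs <- clo:min(d[3], clo + W - 1L)
        tile[seq_along(zs), seq_along(rs), seq_along(cs)] <-
          arr[zs, rs, cs]
        p <- if (is.function(net)) net(tile) else
          predictSegmentation(net, tile)
        forwards <- forwards + 1L
        probs[zs, rs, cs] <- p[seq_along(zs), seq_along(rs), seq_along(cs)]
      }
    }
  }
  mask <- SegmentationMask(array(as.numeric(probs >= probThreshold), d),
                           spacing = sp)
  list(mask = mask, probs = probs, forwards = forwards)
}
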