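# Polar supervision: reference targets for the moving-VOI tracker, the
# corresponding move operator, VOI sampling for training, and geometric
# augmentation that keeps image, mask and path (hence targets) consistent.
#
# Angle convention: theta is measured in array coordinates from the +col
# axis toward the +row axis, in [0, 2*pi). The network-space angle is
# angle_norm = theta/pi - 1 in [-1, 1), matching a tanh output head; the
# [0, 2) scale theta/pi is exposed for reporting.

POLAR_ACTIONS <- c("move", "segment", "stop")

#' Polar-coordinate supervision for one VOI position
#'
#' The reference move is the in-plane displacement from the VOI centre to
#' the same-slice reference-path point: `d` its Euclidean length,
#' `theta = atan2(drow, dcol)` its direction. The radius is capped at the
#' VOI width `W` and normalized to `[0, 1]`. The action is
#' `"segment"` (segment-and-ascend) when `d <= tol`, `"move"` otherwise,
#' and `"stop"` above the annotated path range.
#'
#' @param center VOI centre `(row, col)`.
#' @param z slice index (1-based).
#' @param path a [ReferencePath-class].
#' @param W VOI in-plane width in voxels.
#' @param tol on-path tolerance in voxels.
#' @return List with `angleNorm` in `[-1, 1)`, `radiusNorm` in `[0, 1]`,
#'   `action` (one of "move", "segment", "stop") and `distance` (voxels).
#' @export
polarTargets <- function(center, z, path, W, tol = 8) {
  p <- pathPoint(path, z)
  if (is.null(p))
    return(list(angleNorm = -1, radiusNorm = 0, action = "stop",
                distance = NA_real_))
  drow <- unname(p[1] - center[1]); dcol <- unname(p[2] - center[2])
  d <- sqrt(drow^2 + dcol^2)
  theta <- atan2(drow, dcol) %% (2 * pi)   # degenerate d = 0 gives theta 0
  list(angleNorm = theta / pi - 1,
       radiusNorm = min(d, W) / W,
       action = if (d <= tol) "segment" else "move",
       distance = unname(d))
}

#' Convert a network-space angle to the [0, 2) reporting scale
#' @param angleNorm angle in `[-1, 1)`.
#' @return `theta / pi` in `[0, 2)`.
#' @export
angleNormToScale2 <- function(angleNorm) angleNorm + 1

#' Apply a polar move to a VOI centre
#'
#' `theta = pi * (angleNorm + 1)` and the step length is `radiusNorm * W`;
#' the centre moves
#' by `(r sin(theta), r cos(theta))` in `(row, col)` and is rounded to the
#' nearest voxel.
#'
#' @param center `(row, col)`.
#' @param angleNorm angle in `[-1, 1)`.
#' @param radiusNorm radius in `[0, 1]`, as a fraction of `W`.
#' @param W VOI in-plane width (voxels).
#' @return New `(row, col)` centre (integer-valued).
#' @export
applyPolarMove <- function(center, angleNorm, radiusNorm, W) {
  theta <- pi * (angleNorm + 1)
  r <- radiusNorm * W
  round(c(center[1] + r * sin(theta), center[2] + r * cos(theta)))
}

# ---- VOI cropping ---------------------------------------------------------

# Depth window of a VOI centred at slice zc: zc - D/2 + 1 .. zc + D/2.
voiZRange <- function(zc, D) {
  zlo <- zc - D %/% 2L + 1L
  c(zlo, zlo + D - 1L)
}

voiRowRange <- function(c0, W) {
  lo <- as.integer(round(c0)) - W %/% 2L + 1L
  c(lo, lo + W - 1L)
}

# Zero-padded (D, W, W) crop of a (Z, Y, X) array around centre
# (z, row, col).
voiCrop <- function(arr, zc, crow, ccol, D, W) {
  d <- dim(arr)
  zr <- voiZRange(zc, D); rr <- voiRowRange(crow, W); cr <- voiRowRange(ccol, W)
  out <- array(0, c(D, W, W))
  zs <- max(1L, zr[1]):min(d[1], zr[2])
  rs <- max(1L, rr[1]):min(d[2], rr[2])
  cs <- max(1L, cr[1]):min(d[3], cr[2])
  if (length(zs) && length(rs) && length(cs) &&
      zr[1] <= d[1] && zr[2] >= 1 && rr[1] <= d[2] && rr[2] >= 1 &&
      cr[1] <= d[3] && cr[2] >= 1) {
    out[zs - zr[1] + 1L, rs - rr[1] + 1L, cs - cr[1] + 1L] <-
      arr[zs, rs, cs]
  }
  out
}

# Voxelwise-max paste of a (D, W, W) probability block into `vol`.
voiPasteMax <- function(vol, block, zc, crow, ccol) {
  d <- dim(vol); D <- dim(block)[1]; W <- dim(block)[2]
  zr <- voiZRange(zc, D); rr <- voiRowRange(crow, W); cr <- voiRowRange(ccol, W)
  zs <- max(1L, zr[1]):min(d[1], zr[2])
  rs <- max(1L, rr[1]):min(d[2], rr[2])
  cs <- max(1L, cr[1]):min(d[3], cr[2])
  if (length(zs) && length(rs) && length(cs)) {
    vol[zs, rs, cs] <- pmax(vol[zs, rs, cs],
                            block[zs - zr[1] + 1L, rs - rr[1] + 1L,
                                  cs - cr[1] + 1L])
  }
  vol
}

# True when the whole in-plane extent of the VOI lies inside the volume.
voiInBounds <- function(center, Y, X, W) {
  rr <- voiRowRange(center[1], W); cr <- voiRowRange(center[2], W)
  rr[1] >= 1 && rr[2] <= Y && cr[1] >= 1 && cr[2] <= X
}

# ---- training VOI sampling ------------------------------------------------

#' Sample training VOIs with polar supervision
#'
#' Crops `n` zero-padded VOIs; exactly `round(n * positiveFraction)` of
#' them contain at least one thrombus voxel (negative candidates touching
#' the thrombus are rejected, so the positive fraction is exact by
#' construction). Each VOI carries the polar targets computed at its
#' centre and its relative scan coordinates.
#'
#' @param vol 3D array (preprocessed intensities) or [ImageVolume-class].
#' @param mask 3D array or [SegmentationMask-class] (reference labels).
#' @param path a [ReferencePath-class].
#' @param n number of VOIs.
#' @param positiveFraction fraction of VOIs that must contain thrombus.
#' @param voiShape `(W, W, D)`.
#' @param tol on-path action tolerance (voxels).
#' @param caseId identifier used in error messages.
#' @return List: `vois` (list of (D,W,W) arrays), `segs` (label arrays),
#'   `targets` (data.frame angleNorm/radiusNorm/action/distance), `rel`
#'   (3 x n matrix), `centers` (n x 3 matrix z,row,col).
#' @export
sampleTrainingVois <- function(vol, mask, path, n, positiveFraction = 0.4,
                               voiShape = c(32L, 32L, 8L), tol = 8,
                               caseId = "case") {
  if (is(vol, "ImageVolume")) vol <- voxels(vol)
  if (is(mask, "SegmentationMask")) mask <- voxels(mask)
  W <- voiShape[1]; D <- voiShape[3]
  d <- dim(vol)
  nPos <- round(n * positiveFraction)
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nPos > 0 && nrow(fg) == 0)
    stop("sampleTrainingVois: positive VOIs requested but '", caseId,
         "' has an empty thrombus mask")
  centers <- matrix(0L, n, 3, dimnames = list(NULL, c("z", "row", "col")))
  isPos <- rep(c(TRUE, FALSE), c(nPos, n - nPos))
  for (i in seq_len(n)) {
    if (isPos[i]) {
      for (try in 1:100) {
        v <- fg[sample.int(nrow(fg), 1L), ]
        zc <- v[1] + sample.int(D - 1L, 1L) - D %/% 2L
        rc <- v[2] + sample.int(W - 1L, 1L) - W %/% 2L
        cc <- v[3] + sample.int(W - 1L, 1L) - W %/% 2L
        blk <- voiCrop(mask, zc, rc, cc, D, W)
        if (any(blk != 0)) break
      }
    } else {
      for (try in 1:100) {
        zc <- sample.int(d[1], 1L)
        rc <- sample.int(d[2], 1L)
        cc <- sample.int(d[3], 1L)
        blk <- voiCrop(mask, zc, rc, cc, D, W)
        if (!any(blk != 0)) break
      }
    }
    centers[i, ] <- c(zc, rc, cc)
  }
  ord <- sample.int(n)
  centers <- centers[ord, , drop = FALSE]
  isPos <- isPos[ord]
  vois <- vector("list", n); segs <- vector("list", n)
  tg <- vector("list", n)
  rel <- matrix(0, 3, n)
  for (i in seq_len(n)) {
    zc <- centers[i, 1]; rc <- centers[i, 2]; cc <- centers[i, 3]
    vois[[i]] <- voiCrop(vol, zc, rc, cc, D, W)
    segs[[i]] <- voiCrop(mask, zc, rc, cc, D, W)
    tg[[i]] <- polarTargets(c(rc, cc), zc, path, W, tol)
    rel[, i] <- pmin(pmax(c(zc / d[1], rc / d[2], cc / d[3]), 0), 1)
  }
  targets <- data.frame(
    angleNorm = vapply(tg, `[[`, numeric(1), "angleNorm"),
    radiusNorm = vapply(tg, `[[`, numeric(1), "radiusNorm"),
    action = vapply(tg, `[[`, character(1), "action"),
    distance = vapply(tg, `[[`, numeric(1), "distance"),
    stringsAsFactors = FALSE)
  list(vois = vois, segs = segs, targets = targets, rel = rel,
       centers = centers, positive = isPos)
}

# ---- augmentation ---------------------------------------------------------

#' Draw augmentation parameters
#'
#' In-plane rotation between `rotRange` degrees, left-right flip with
#' probability `flipProb`, magnification in `zoomRange`, and an axial
#' translation of at most `maxShift` voxels per axis.
#'
#' @param rotRange rotation range in degrees.
#' @param flipProb probability of a left-right flip.
#' @param zoomRange magnification range.
#' @param maxShift maximal in-plane translation (voxels).
#' @return List of parameters for [augmentCase()].
#' @export
drawAugmentParams <- function(rotRange = c(-10, 10), flipProb = 0.5,
                              zoomRange = c(0.9, 1.1), maxShift = 80) {
  list(rotDeg = runif(1, rotRange[1], rotRange[2]),
       flip = runif(1) < flipProb,
       zoom = runif(1, zoomRange[1], zoomRange[2]),
       shift = runif(2, -maxShift, maxShift))
}

identityAugmentParams <- function() {
  list(rotDeg = 0, flip = FALSE, zoom = 1, shift = c(0, 0))
}

# Forward map of a point (row, col) under the augmentation parameters,
# about the in-plane centre of a (Y, X) slice.
augmentMapPoint <- function(pts, params, Y, X) {
  pts <- matrix(pts, ncol = 2)
  yc <- (Y + 1) / 2; xc <- (X + 1) / 2
  r <- pts[, 1]; cc <- pts[, 2]
  if (params$flip) cc <- (X + 1) - cc
  phi <- params$rotDeg * pi / 180
  vr <- r - yc; vc <- cc - xc
  nr <- params$zoom * (cos(phi) * vr + sin(phi) * vc)
  nc <- params$zoom * (-sin(phi) * vr + cos(phi) * vc)
  cbind(yc + nr + params$shift[1], xc + nc + params$shift[2])
}

# Inverse map: target grid -> source coordinates.
augmentInverseGrid <- function(params, Y, X) {
  yc <- (Y + 1) / 2; xc <- (X + 1) / 2
  q <- cbind(rep(seq_len(Y), X) - yc - params$shift[1],
             rep(seq_len(X), each = Y) - xc - params$shift[2])
  phi <- -params$rotDeg * pi / 180
  s <- 1 / params$zoom
  vr <- s * (cos(phi) * q[, 1] + sin(phi) * q[, 2])
  vc <- s * (-sin(phi) * q[, 1] + cos(phi) * q[, 2])
  r <- yc + vr; cc <- xc + vc
  if (params$flip) cc <- (X + 1) - cc
  cbind(r, cc)
}

# Per-slice resampling with a shared in-plane map. Bilinear for images,
# nearest neighbour for masks.
resampleSlices <- function(arr, params, interp = c("bilinear", "nearest"),
                           fill = NA) {
  interp <- match.arg(interp)
  d <- dim(arr)
  if (is.na(fill)) fill <- min(arr)
  src <- augmentInverseGrid(params, d[2], d[3])
  # all slices share the in-plane map: operate on the (Z x Y*X) view
  am <- matrix(arr, d[1])
  om <- matrix(fill, d[1], d[2] * d[3])
  if (interp == "nearest") {
    r <- round(src[, 1]); cc <- round(src[, 2])
    ok <- r >= 1 & r <= d[2] & cc >= 1 & cc <= d[3]
    om[, ok] <- am[, r[ok] + (cc[ok] - 1) * d[2], drop = FALSE]
  } else {
    r0 <- floor(src[, 1]); c0 <- floor(src[, 2])
    fr <- src[, 1] - r0; fc <- src[, 2] - c0
    ok <- r0 >= 1 & r0 + 1 <= d[2] & c0 >= 1 & c0 + 1 <= d[3]
    i00 <- r0[ok] + (c0[ok] - 1) * d[2]
    w00 <- (1 - fr[ok]) * (1 - fc[ok]); w10 <- fr[ok] * (1 - fc[ok])
    w01 <- (1 - fr[ok]) * fc[ok]; w11 <- fr[ok] * fc[ok]
    om[, ok] <- am[, i00, drop = FALSE] *
      rep(w00, each = d[1]) +
      am[, i00 + 1, drop = FALSE] * rep(w10, each = d[1]) +
      am[, i00 + d[2], drop = FALSE] * rep(w01, each = d[1]) +
      am[, i00 + d[2] + 1, drop = FALSE] * rep(w11, each = d[1])
  }
  array(om, d)
}

#' Jointly augment a volume, mask and reference path
#'
#' Applies one in-plane rotation / flip / magnification / translation to
#' the image (bilinear), the mask (nearest neighbour) and the path points
#' (exact coordinate transform), so polar targets recomputed from the
#' augmented path are consistent with the augmented image.
#'
#' @param vol 3D array or [ImageVolume-class].
#' @param mask 3D array or [SegmentationMask-class] (may be `NULL`).
#' @param path a [ReferencePath-class] (may be `NULL`).
#' @param params augmentation parameters ([drawAugmentParams()]); drawn
#'   from the current RNG when `NULL`.
#' @param ... passed to [drawAugmentParams()].
#' @return List `vol`, `mask`, `path`, `params` (arrays in, arrays out).
#' @export
augmentCase <- function(vol, mask = NULL, path = NULL, params = NULL, ...) {
  isVolObj <- is(vol, "ImageVolume")
  sp <- if (isVolObj) spacing(vol) else NULL
  if (isVolObj) vol <- voxels(vol)
  isMaskObj <- is(mask, "SegmentationMask")
  mspc <- if (isMaskObj) spacing(mask) else NULL
  if (isMaskObj) mask <- voxels(mask)
  if (is.null(params)) params <- drawAugmentParams(...)
  d <- dim(vol)
  ident <- params$rotDeg == 0 && !params$flip && params$zoom == 1 &&
    all(params$shift == 0)
  outVol <- if (ident) vol else resampleSlices(vol, params, "bilinear")
  outMask <- if (is.null(mask)) NULL else if (ident) mask else
    resampleSlices(mask, params, "nearest", fill = 0)
  outPath <- path
  if (!is.null(path) && !ident) {
    pts <- augmentMapPoint(path@points, params, d[2], d[3])
    outPath <- ReferencePath(pts, zMin = path@zMin)
  }
  if (isVolObj) outVol <- ImageVolume(outVol, spacing = sp)
  if (isMaskObj && !is.null(outMask))
    outMask <- SegmentationMask(outMask, spacing = mspc)
  list(vol = outVol, mask = outMask, path = outPath, params = params)
}
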