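# BL-UNet: a 3D residual U-Net over a (W, W, D) volume-of-interest.
# Polar-UNet: the same backbone plus regression/classification heads fed by
# globally average-pooled features from four levels of the down-sampling
# path, concatenated with the VOI's relative position in the scan.

#' Network configuration
#'
#' @param voiShape VOI dimensions as (W, W, D): in-plane side length W and
#'   depth D in voxels. W and D must be divisible by 8 (three stride-2
#'   poolings). Stored internally as (z, y, x) = (D, W, W).
#' @param baseChannels channels of the first level; doubled per level
#'   (divisible by the number of normalization groups).
#' @param groups group-normalization group count for the backbone.
#' @param headHidden width of the two shared fully connected head layers.
#' @return A list of class `"NetConfig"`.
#' @export
netConfig <- function(voiShape = c(192L, 192L, 8L), baseChannels = 32L,
                      groups = 4L, headHidden = 256L) {
  W <- voiShape[1]; D <- voiShape[3]
  if (voiShape[2] != W) stop("netConfig: VOI must be square in-plane")
  if (W %% 8 != 0 || D %% 8 != 0)
    stop("netConfig: VOI dimensions must be divisible by the total pooling ",
         "factor 8")
  if (baseChannels %% groups != 0)
    stop("netConfig: baseChannels must be divisible by groups")
  structure(list(W = as.integer(W), D = as.integer(D),
                 sp = as.integer(c(D, W, W)),
                 baseChannels = as.integer(baseChannels),
                 groups = as.integer(groups),
                 headHidden = as.integer(headHidden)),
            class = "NetConfig")
}

#' Desk-scale network configuration
#'
#' Small profile (VOI 32 x 32 x 8, 8 base channels) exercising the same
#' code paths as the full-scale configuration in minutes on a CPU.
#' @return A `"NetConfig"`.
#' @export
deskNetConfig <- function() netConfig(c(32L, 32L, 8L), baseChannels = 8L)

#' Build a randomly initialized BL-UNet
#'
#' Down path: two k3 s1 convolutions (stem), a k2 s2 max-pool, then three
#' residual blocks with pooling after the first two. Up path: a transposed
#' convolution (k3 s2), then twice (residual block + transposed
#' convolution), with skip concatenations from the matching down-path
#' levels; head: k3 convolution, k1 convolution, per-voxel sigmoid. All
#' backbone normalizations are group norm.
#'
#' @param cfg a [netConfig()].
#' @param seed integer seed for the weight initialization.
#' @return A list of class `"BlUnet"` with fields `cfg` and `P` (parameter
#'   environment).
#' @export
buildBlUnet <- function(cfg = netConfig(), seed = 1L) {
  C <- cfg$baseChannels
  P <- newParamEnv()
  withSeed(seed, {
    convParamsInit(P, "stem.c1", 1L, C); normParamsInit(P, "stem.n1", C)
    convParamsInit(P, "stem.c2", C, C); normParamsInit(P, "stem.n2", C)
    resParamsInit(P, "res1", C, 2L * C)
    resParamsInit(P, "res2", 2L * C, 4L * C)
    resParamsInit(P, "res3", 4L * C, 8L * C)
    tconvParamsInit(P, "up1.t", 8L * C, 4L * C)
    resParamsInit(P, "ur1", 8L * C, 4L * C)
    tconvParamsInit(P, "up2.t", 4L * C, 2L * C)
    resParamsInit(P, "ur2", 4L * C, 2L * C)
    tconvParamsInit(P, "up3.t", 2L * C, C)
    convParamsInit(P, "head.c1", 2L * C, C); normParamsInit(P, "head.n1", C)
    convParamsInit(P, "head.c2", C, 1L, k = 1L)
    # prior initialization of the output bias: start near the foreground
    # base rate so the focal loss does not spend early iterations
    # suppressing the background (standard for this loss family)
    P[["head.c2.b"]] <- log(0.01 / 0.99)
  })
  structure(list(cfg = cfg, P = P), class = "BlUnet")
}

resParamsInit <- function(P, nm, cin, cout) {
  convParamsInit(P, paste0(nm, ".c1"), cin, cout)
  normParamsInit(P, paste0(nm, ".n1"), cout)
  convParamsInit(P, paste0(nm, ".c2"), cout, cout)
  normParamsInit(P, paste0(nm, ".n2"), cout)
  if (cin != cout) convParamsInit(P, paste0(nm, ".proj"), cin, cout, k = 1L)
  invisible(P)
}

resBlockFwd <- function(P, nm, tin, groups, cache) {
  a <- convFwd(P, paste0(nm, ".c1"), tin, cache = cache)
  a <- gnFwd(P, paste0(nm, ".n1"), a, groups, cache)
  a <- reluFwd(paste0(nm, ".r1"), a, cache)
  b <- convFwd(P, paste0(nm, ".c2"), a, cache = cache)
  b <- gnFwd(P, paste0(nm, ".n2"), b, groups, cache)
  hasProj <- !is.null(P[[paste0(nm, ".proj.w")]])
  sc <- if (hasProj) convFwd(P, paste0(nm, ".proj"), tin, k = 1L,
                             cache = cache) else tin
  y <- nnTensor(b$x + sc$x, b$sp, b$n)
  reluFwd(paste0(nm, ".r2"), y, cache)
}

resBlockBwd <- function(P, G, nm, cache, dY) {
  d <- reluBwd(paste0(nm, ".r2"), cache, dY)
  db <- gnBwd(P, G, paste0(nm, ".n2"), cache, d)
  da <- convBwd(P, G, paste0(nm, ".c2"), cache, db)
  da <- reluBwd(paste0(nm, ".r1"), cache, da)
  da <- gnBwd(P, G, paste0(nm, ".n1"), cache, da)
  dx <- convBwd(P, G, paste0(nm, ".c1"), cache, da)
  hasProj <- !is.null(P[[paste0(nm, ".proj.w")]])
  dsc <- if (hasProj) convBwd(P, G, paste0(nm, ".proj"), cache, d, k = 1L)
         else d
  nnTensor(dx$x + dsc$x, dx$sp, dx$n)
}

# Down-sampling path: returns the four level features.
blFwdDown <- function(net, tin, cache = NULL) {
  P <- net$P; g <- net$cfg$groups
  if (!identical(tin$sp, net$cfg$sp))
    stop("network/VOI shape mismatch: VOI is ",
         paste(tin$sp, collapse = "x"), ", network expects ",
         paste(net$cfg$sp, collapse = "x"))
  t0 <- convFwd(P, "stem.c1", tin, cache = cache)
  t0 <- gnFwd(P, "stem.n1", t0, g, cache)
  t0 <- reluFwd("stem.r1", t0, cache)
  t0 <- convFwd(P, "stem.c2", t0, cache = cache)
  t0 <- gnFwd(P, "stem.n2", t0, g, cache)
  f0 <- reluFwd("stem.r2", t0, cache)
  p0 <- poolFwd("pool0", f0, cache)
  f1 <- resBlockFwd(P, "res1", p0, g, cache)
  p1 <- poolFwd("pool1", f1, cache)
  f2 <- resBlockFwd(P, "res2", p1, g, cache)
  p2 <- poolFwd("pool2", f2, cache)
  f3 <- resBlockFwd(P, "res3", p2, g, cache)
  list(f0 = f0, f1 = f1, f2 = f2, f3 = f3)
}

# Up-sampling path and segmentation head, from the down-path features.
blFwdUp <- function(net, feats, cache = NULL) {
  P <- net$P; g <- net$cfg$groups
  u1 <- tconvFwd(P, "up1.t", feats$f3, cache = cache)
  r1 <- resBlockFwd(P, "ur1", concatFwd(u1, feats$f2), g, cache)
  u2 <- tconvFwd(P, "up2.t", r1, cache = cache)
  r2 <- resBlockFwd(P, "ur2", concatFwd(u2, feats$f1), g, cache)
  u3 <- tconvFwd(P, "up3.t", r2, cache = cache)
  h <- convFwd(P, "head.c1", concatFwd(u3, feats$f0), cache = cache)
  h <- gnFwd(P, "head.n1", h, g, cache)
  h <- reluFwd("head.r1", h, cache)
  logits <- convFwd(P, "head.c2", h, k = 1L, cache = cache)
  list(probs = nnTensor(sigmoidMat(logits$x), logits$sp, logits$n),
       logits = logits)
}

# Full forward pass. Returns seg probabilities plus (optionally) the four
# down-path feature tensors.
blFwd <- function(net, tin, cache = NULL, wantFeatures = FALSE) {
  feats <- blFwdDown(net, tin, cache)
  out <- blFwdUp(net, feats, cache)
  if (wantFeatures) out$features <- feats
  out
}

# Backward from d(loss)/d(logits); accumulates parameter grads into G.
blBwd <- function(net, G, cache, dLogits) {
  P <- net$P
  dh <- convBwd(P, G, "head.c2", cache, dLogits, k = 1L)
  dh <- reluBwd("head.r1", cache, dh)
  dh <- gnBwd(P, G, "head.n1", cache, dh)
  dcat <- convBwd(P, G, "head.c1", cache, dh)
  C <- net$cfg$baseChannels
  sp3 <- concatBwd(dcat, C)
  du3 <- sp3[[1]]; df0a <- sp3[[2]]
  dr2 <- tconvBwd(P, G, "up3.t", cache, du3)
  dc2 <- resBlockBwd(P, G, "ur2", cache, dr2)
  sp2 <- concatBwd(dc2, 2L * C)
  du2 <- sp2[[1]]; df1a <- sp2[[2]]
  dr1 <- tconvBwd(P, G, "up2.t", cache, du2)
  dc1 <- resBlockBwd(P, G, "ur1", cache, dr1)
  sp1 <- concatBwd(dc1, 4L * C)
  du1 <- sp1[[1]]; df2a <- sp1[[2]]
  df3 <- tconvBwd(P, G, "up1.t", cache, du1)
  dp2 <- resBlockBwd(P, G, "res3", cache, df3)
  df2 <- poolBwd("pool2", cache, dp2)
  df2 <- nnTensor(df2$x + df2a$x, df2$sp, df2$n)
  dp1 <- resBlockBwd(P, G, "res2", cache, df2)
  df1 <- poolBwd("pool1", cache, dp1)
  df1 <- nnTensor(df1$x + df1a$x, df1$sp, df1$n)
  dp0 <- resBlockBwd(P, G, "res1", cache, df1)
  df0 <- poolBwd("pool0", cache, dp0)
  df0 <- nnTensor(df0$x + df0a$x, df0$sp, df0$n)
  d <- reluBwd("stem.r2", cache, df0)
  d <- gnBwd(P, G, "stem.n2", cache, d)
  d <- convBwd(P, G, "stem.c2", cache, d)
  d <- reluBwd("stem.r1", cache, d)
  d <- gnBwd(P, G, "stem.n1", cache, d)
  convBwd(P, G, "stem.c1", cache, d)
}

#' Build a Polar-UNet on a (pre-trained) BL-UNet backbone
#'
#' The backbone (down path, up path and segmentation head) is reused and
#' frozen. Features from the four down-path levels each pass one k3
#' convolution (base-channel width) with batch normalization and ReLU, are
#' globally average-pooled, concatenated with the VOI's relative (z, y, x)
#' coordinates, passed through two shared 256-unit fully connected layers,
#' and feed three heads: angle (tanh), radius (sigmoid) and a 3-class
#' action classifier (softmax). Layers added here use batch normalization.
#'
#' @param backbone a `"BlUnet"` (typically trained).
#' @param seed seed for head initialization.
#' @return A list of class `"PolarUnet"` with fields `cfg`, `P` and
#'   `trainable` (names of head parameters).
#' @export
buildPolarUnet <- function(backbone, seed = 1L) {
  stopifnot(inherits(backbone, "BlUnet"))
  cfg <- backbone$cfg
  C <- cfg$baseChannels
  P <- newParamEnv()
  for (nm in ls(backbone$P)) P[[nm]] <- backbone$P[[nm]]
  backboneNames <- ls(P)
  withSeed(seed, {
    lvl <- c(1L, 2L, 4L, 8L)
    for (i in 0:3) {
      convParamsInit(P, sprintf("ph.f%d.c", i), lvl[i + 1] * C, C)
      normParamsInit(P, sprintf("ph.f%d.bn", i), C, batch = TRUE)
    }
    fcParamsInit(P, "ph.fc1", 4L * C + 3L, cfg$headHidden)
    normParamsInit(P, "ph.fc1bn", cfg$headHidden, batch = TRUE)
    fcParamsInit(P, "ph.fc2", cfg$headHidden, cfg$headHidden)
    normParamsInit(P, "ph.fc2bn", cfg$headHidden, batch = TRUE)
    fcParamsInit(P, "out.ang", cfg$headHidden, 1L)
    fcParamsInit(P, "out.rad", cfg$headHidden, 1L)
    fcParamsInit(P, "out.act", cfg$headHidden, 3L)
  })
  trainable <- setdiff(ls(P), backboneNames)
  structure(list(cfg = cfg, P = P, trainable = trainable),
            class = "PolarUnet")
}

softmaxCols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Polar heads on precomputed down-path features.
polarHeadsFwd <- function(net, feats, rel, cache = NULL, train = FALSE) {
  rel <- matrix(rel, nrow = 3)
  if (any(rel < 0) || any(rel > 1))
    stop("polarFwd: relative coordinates must lie in [0, 1]^3")
  P <- net$P
  gaps <- vector("list", 4L)
  spInfo <- vector("list", 4L)
  for (i in 0:3) {
    f <- feats[[i + 1]]
    h <- convFwd(P, sprintf("ph.f%d.c", i), f, cache = cache)
    h <- bnFwd(P, sprintf("ph.f%d.bn", i), h, train, cache)
    h <- reluFwd(sprintf("ph.f%d.r", i), h, cache)
    gaps[[i + 1]] <- gapFwd(h)
    spInfo[[i + 1]] <- list(sp = h$sp, n = h$n)
  }
  feat <- rbind(do.call(rbind, gaps), rel)
  z1 <- fcFwd(P, "ph.fc1", feat, cache)
  z1 <- bnFwd(P, "ph.fc1bn", nnTensor(z1, c(1, 1, 1), ncol(z1)), train,
              cache)$x
  r1m <- z1 > 0; z1 <- pmax(z1, 0)
  z2 <- fcFwd(P, "ph.fc2", z1, cache)
  z2 <- bnFwd(P, "ph.fc2bn", nnTensor(z2, c(1, 1, 1), ncol(z2)), train,
              cache)$x
  r2m <- z2 > 0; z2 <- pmax(z2, 0)
  za <- fcFwd(P, "out.ang", z2, cache)
  zr <- fcFwd(P, "out.rad", z2, cache)
  zc <- fcFwd(P, "out.act", z2, cache)
  if (!is.null(cache)) {
    cache[["ph.relu1"]] <- list(mask = r1m)
    cache[["ph.relu2"]] <- list(mask = r2m)
    cache[["ph.spInfo"]] <- spInfo
    cache[["ph.gapsDim"]] <- vapply(gaps, nrow, integer(1))
  }
  list(angle = tanh(as.vector(za)),
       radius = as.vector(sigmoidMat(zr)),
       actionProbs = softmaxCols(zc))
}

# Forward pass of the polar heads (and the frozen backbone).
# rel: 3 x n matrix of relative (z, y, x) VOI-centre coordinates in [0,1].
polarFwd <- function(net, tin, rel, cache = NULL, train = FALSE,
                     wantSeg = TRUE) {
  feats <- blFwdDown(net, tin, cache = NULL)
  out <- polarHeadsFwd(net, feats, rel, cache, train)
  out$segProbs <- if (wantSeg) blFwdUp(net, feats, cache = NULL)$probs
                  else NULL
  out
}

# Backward through the polar heads only (backbone frozen). Inputs are the
# gradients w.r.t. the three pre-activation head outputs.
polarBwd <- function(net, G, cache, dza, dzr, dzc) {
  P <- net$P
  dz2 <- fcBwd(P, G, "out.ang", cache, matrix(dza, nrow = 1)) +
    fcBwd(P, G, "out.rad", cache, matrix(dzr, nrow = 1)) +
    fcBwd(P, G, "out.act", cache, dzc)
  dz2 <- dz2 * cache[["ph.relu2"]]$mask
  n <- ncol(dz2)
  dz2 <- bnBwd(P, G, "ph.fc2bn", cache, nnTensor(dz2, c(1, 1, 1), n))$x
  dz1 <- fcBwd(P, G, "ph.fc2", cache, dz2)
  dz1 <- dz1 * cache[["ph.relu1"]]$mask
  dz1 <- bnBwd(P, G, "ph.fc1bn", cache, nnTensor(dz1, c(1, 1, 1), n))$x
  dfeat <- fcBwd(P, G, "ph.fc1", cache, dz1)
  gd <- cache[["ph.gapsDim"]]
  ofs <- cumsum(c(0, gd))
  for (i in 0:3) {
    rows <- (ofs[i + 1] + 1):ofs[i + 2]
    inf <- cache[["ph.spInfo"]][[i + 1]]
    dgap <- gapBwd(dfeat[rows, , drop = FALSE], inf$sp, inf$n)
    d <- reluBwd(sprintf("ph.f%d.r", i), cache, dgap)
    d <- bnBwd(P, G, sprintf("ph.f%d.bn", i), cache, d)
    convBwd(P, G, sprintf("ph.f%d.c", i), cache, d)  # gradient stops here
  }
  invisible(G)
}

#' Segment one VOI with a network
#'
#' @param net a `"BlUnet"` or `"PolarUnet"`.
#' @param voi a (D, W, W) array (preprocessed intensities).
#' @return Array of per-voxel thrombus probabilities, same shape.
#' @export
predictSegmentation <- function(net, voi) {
  tin <- arrayToTensor(voi)
  out <- blFwd(net, tin)
  tensorToArrays(out$probs)[[1]]
}

#' Run the polar heads on one VOI
#'
#' Accepts either a `"PolarUnet"` or a plain function
#' `f(voi, rel) -> list(angle, radius, actionProbs, segProbs)` (used e.g.
#' for reference-target oracle networks in tests).
#'
#' @param net network or function.
#' @param voi (D, W, W) array.
#' @param rel relative VOI-centre coordinates (z, y, x) in `[0, 1]^3`.
#' @return List with `angle` in `[-1, 1]`, `radius` in `[0, 1]`,
#'   `actionProbs` (3-vector: move, segment-ascend, stop) and `segProbs`.
#' @export
predictPolar <- function(net, voi, rel) {
  if (any(rel < 0) || any(rel > 1))
    stop("predictPolar: relative coordinates must lie in [0, 1]^3")
  if (is.function(net)) return(net(voi, rel))
  out <- polarFwd(net, arrayToTensor(voi), matrix(rel, 3, 1))
  list(angle = out$angle, radius = out$radius,
       actionProbs = as.vector(out$actionProbs),
       segProbs = tensorToArrays(out$segProbs)[[1]])
}

#' Save / load a network checkpoint
#'
#' A single file with the configuration embedded.
#' @param net a `"BlUnet"` or `"PolarUnet"`.
#' @param path checkpoint file path.
#' @return `path` / the restored network.
#' @export
saveCheckpoint <- function(net, path) {
  obj <- list(class = class(net), cfg = net$cfg,
              params = paramSnapshot(net$P), trainable = net$trainable)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  P <- newParamEnv()
  for (nm in names(obj$params)) P[[nm]] <- obj$params[[nm]]
  net <- list(cfg = obj$cfg, P = P)
  if (!is.null(obj$trainable)) net$trainable <- obj$trainable
  structure(net, class = obj$class)
}
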