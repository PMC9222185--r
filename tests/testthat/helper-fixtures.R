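# Shared fixtures and independent oracles, all built in code.

# Small phantom spec used across tests (fast to generate).
tinySpec <- function(seed = 1L, ...) {
  phantomSpec(shape = c(32L, 64L, 64L), spacing = c(2, 0.5, 0.5),
              seed = seed, ...)
}

# Memoised default-size phantom (several tests share one case).
defaultCase <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7L) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generatePhantom(phantomSpec(seed = seed))
    cache[[key]]
  }
})

# Independent flood-fill connected-component labelling (R, queue-based),
# used as the oracle for the C++ implementation.
floodLabel <- function(arr, connectivity = 26) {
  d <- dim(arr)
  offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  offs <- offs[!(offs$a == 0 & offs$b == 0 & offs$c == 0), ]
  nz <- abs(offs$a) + abs(offs$b) + abs(offs$c)
  offs <- offs[nz <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)], ]
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(arr != 0, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    p <- idx[s, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    cur <- cur + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- cur
    while (length(queue)) {
      q <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (t in seq_len(nrow(offs))) {
        r <- q + c(offs$a[t], offs$b[t], offs$c[t])
        if (any(r < 1) || any(r > d)) next
        if (arr[r[1], r[2], r[3]] != 0 && lab[r[1], r[2], r[3]] == 0L) {
          lab[r[1], r[2], r[3]] <- cur
          queue[[length(queue) + 1L]] <- r
        }
      }
    }
  }
  lab
}

# Brute-force component matching oracle: all-pairs voxel enumeration over
# independently labelled masks.
bruteMatch <- function(refArr, predArr, overlapFrac = 0.10,
                       connectivity = 26) {
  labR <- floodLabel(refArr, connectivity)
  labP <- floodLabel(predArr, connectivity)
  nR <- max(labR); nP <- max(labP)
  refMatched <- logical(nR); predMatched <- logical(nP)
  for (r in seq_len(nR)) for (p in seq_len(nP)) {
    vr <- labR == r; vp <- labP == p
    ov <- sum(vr & vp)
    if (ov / sum(vr) >= overlapFrac) refMatched[r] <- TRUE
    if (ov / sum(vp) >= overlapFrac) predMatched[p] <- TRUE
  }
  list(tpRef = sum(refMatched), fn = sum(!refMatched),
       tpPred = sum(predMatched), fp = sum(!predMatched),
       nRef = nR, nPred = nP)
}

# Random blob mask for matching tests.
randomBlobMask <- function(d = c(16L, 16L, 16L), nBlobs = 3L, pDrop = 0.3) {
  arr <- array(0, d)
  for (i in seq_len(nBlobs)) {
    ctr <- sapply(d, function(x) sample.int(x, 1))
    rad <- sample(1:3, 1)
    rng <- lapply(1:3, function(a)
      max(1, ctr[a] - rad):min(d[a], ctr[a] + rad))
    arr[rng[[1]], rng[[2]], rng[[3]]] <- 1
  }
  drop <- runif(length(arr)) < pDrop
  arr[drop] <- 0
  arr
}

# An oracle "network" that emits the reference polar targets and the
# reference segmentation crop (the supervision module plugged in as a fake
# network).
oracleNet <- function(case, W = 32L, D = 8L, tol = 8) {
  msk <- voxels(case@thrombus)
  d <- dim(msk)
  pth <- case@path
  function(voi, rel) {
    z <- round(rel[1] * d[1])
    r <- rel[2] * d[2]; cc <- rel[3] * d[3]
    tg <- polarTargets(c(r, cc), z, pth, W, tol = tol)
    a <- c(move = 0, segment = 0, stop = 0)
    a[tg$action] <- 1
    list(angle = tg$angleNorm, radius = tg$radiusNorm,
         actionProbs = unname(a),
         segProbs = polartrack:::voiCrop(msk, z, r, cc, D, W))
  }
}
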