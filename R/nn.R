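# Minimal 3D CNN engine: batched tensors as C x (S*N) matrices (rows =
# channels, columns = voxels sample-by-sample, spatial order = R array
# order over dims (z, y, x)), layers with explicit forward/backward, and
# Adam. Convolutions run as im2col + BLAS GEMM through the C++ kernels.
# Every backward pass is covered by finite-difference gradient checks in
# the test suite.

nnTensor <- function(x, sp, n) list(x = x, sp = as.integer(sp), n = as.integer(n))

# Convert a (D, W, W) array (or a batch list of them) into a tensor with C
# channels along rows. For single-channel input x is a plain array.
arrayToTensor <- function(arrs) {
  if (!is.list(arrs)) arrs <- list(arrs)
  sp <- dim(arrs[[1]])
  x <- matrix(unlist(arrs, use.names = FALSE), nrow = 1)
  nnTensor(x, sp, length(arrs))
}

tensorToArrays <- function(t, channel = 1L) {
  S <- prod(t$sp)
  lapply(seq_len(t$n), function(b)
    array(t$x[channel, ((b - 1) * S + 1):(b * S)], t$sp))
}

heInit <- function(nout, nin) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

# ---- conv (k3 pad1 stride1 and k1) ---------------------------------------

convParamsInit <- function(P, nm, cin, cout, k = 3L) {
  P[[paste0(nm, ".w")]] <- heInit(cout, cin * k^3)
  P[[paste0(nm, ".b")]] <- numeric(cout)
  invisible(P)
}

convFwd <- function(P, nm, tin, k = 3L, cache = NULL, chunkCols = 2^25) {
  W <- P[[paste0(nm, ".w")]]; b <- P[[paste0(nm, ".b")]]
  if (k == 1L) {
    y <- W %*% tin$x + b
    if (!is.null(cache)) cache[[nm]] <- list(xin = tin)
    return(nnTensor(y, tin$sp, tin$n))
  }
  k3 <- rep(k, 3); s1 <- rep(1L, 3); p1 <- rep((k - 1L) %/% 2L, 3)
  nIn <- nrow(tin$x)
  if (is.null(cache) && as.double(nIn) * k^3 * ncol(tin$x) > chunkCols) {
    # memory-bounded inference path: per sample, then x-slabs
    if (tin$n > 1L) {
      S <- prod(tin$sp)
      parts <- lapply(seq_len(tin$n), function(b) {
        sub <- nnTensor(tin$x[, ((b - 1) * S + 1):(b * S), drop = FALSE],
                        tin$sp, 1L)
        convFwd(P, nm, sub, k = k, cache = NULL, chunkCols = chunkCols)$x
      })
      return(nnTensor(do.call(cbind, parts), tin$sp, tin$n))
    }
    y <- matrix(0, nrow(W), ncol(tin$x))
    d <- tin$sp
    plane <- d[1] * d[2]
    slab <- max(1L, as.integer(chunkCols / (nIn * k^3 * plane)))
    h <- (k - 1L) %/% 2L   # halo width along x
    for (lo in seq(1L, d[3], by = slab)) {
      hi <- min(d[3], lo + slab - 1L)
      ilo <- max(1L, lo - h); ihi <- min(d[3], hi + h)
      sub <- tin$x[, ((ilo - 1) * plane + 1):(ihi * plane), drop = FALSE]
      subDims <- c(d[1], d[2], ihi - ilo + 1L)
      # full same-padding on the slab; keep only centre planes (the halo
      # planes would wrongly see zero padding, the volume edges correctly do)
      cols <- im2col3(sub, subDims, 1L, k3, s1, p1)
      keep <- ((lo - ilo) * plane + 1):((hi - ilo + 1L) * plane)
      y[, ((lo - 1) * plane + 1):(hi * plane)] <-
        W %*% cols[, keep, drop = FALSE]
    }
    y <- y + b
    return(nnTensor(y, tin$sp, tin$n))
  }
  cols <- im2col3(tin$x, tin$sp, tin$n, k3, s1, p1)
  y <- W %*% cols + b
  if (!is.null(cache))
    cache[[nm]] <- list(cols = cols, sp = tin$sp, n = tin$n, cin = nIn)
  nnTensor(y, tin$sp, tin$n)
}

convBwd <- function(P, G, nm, cache, dY, k = 3L) {
  W <- P[[paste0(nm, ".w")]]
  cc <- cache[[nm]]
  if (k == 1L) {
    addGrad(G, paste0(nm, ".w"), tcrossprod(dY$x, cc$xin$x))
    addGrad(G, paste0(nm, ".b"), rowSums(dY$x))
    return(nnTensor(crossprod(W, dY$x), dY$sp, dY$n))
  }
  addGrad(G, paste0(nm, ".w"), tcrossprod(dY$x, cc$cols))
  addGrad(G, paste0(nm, ".b"), rowSums(dY$x))
  dcols <- crossprod(W, dY$x)
  k3 <- rep(k, 3); s1 <- rep(1L, 3); p1 <- rep((k - 1L) %/% 2L, 3)
  dx <- col2im3(dcols, cc$cin, cc$sp, cc$n, k3, s1, p1)
  nnTensor(dx, cc$sp, cc$n)
}

# ---- transposed conv k3, stride 2, output = 2x input ----------------------

tconvParamsInit <- function(P, nm, cin, cout, k = 3L) {
  P[[paste0(nm, ".w")]] <- heInit(cout * k^3, cin)
  P[[paste0(nm, ".b")]] <- numeric(cout)
  invisible(P)
}

tconvFwd <- function(P, nm, tin, stride = c(2L, 2L, 2L), k = 3L,
                     cache = NULL) {
  W <- P[[paste0(nm, ".w")]]; b <- P[[paste0(nm, ".b")]]
  cout <- length(b)
  spOut <- tin$sp * stride
  cols <- W %*% tin$x
  k3 <- rep(k, 3); p1 <- rep(1L, 3)
  y <- col2im3(cols, cout, spOut, tin$n, k3, as.integer(stride), p1)
  y <- y + b
  if (!is.null(cache))
    cache[[nm]] <- list(xin = tin, spOut = spOut, stride = as.integer(stride))
  nnTensor(y, spOut, tin$n)
}

tconvBwd <- function(P, G, nm, cache, dY, k = 3L) {
  W <- P[[paste0(nm, ".w")]]
  cc <- cache[[nm]]
  k3 <- rep(k, 3); p1 <- rep(1L, 3)
  dcols <- im2col3(dY$x, cc$spOut, dY$n, k3, cc$stride, p1)
  addGrad(G, paste0(nm, ".w"), tcrossprod(dcols, cc$xin$x))
  addGrad(G, paste0(nm, ".b"), rowSums(dY$x))
  nnTensor(crossprod(W, dcols), cc$xin$sp, cc$xin$n)
}

# ---- max pooling k2 s2 ----------------------------------------------------

poolFwd <- function(nm, tin, cache = NULL, k = c(2L, 2L, 2L)) {
  res <- maxpool3_fwd(tin$x, tin$sp, tin$n, k, k)
  spOut <- tin$sp %/% k
  if (!is.null(cache))
    cache[[nm]] <- list(idx = res$idx, ncolIn = ncol(tin$x), sp = tin$sp)
  nnTensor(res$y, spOut, tin$n)
}

poolBwd <- function(nm, cache, dY) {
  cc <- cache[[nm]]
  nnTensor(maxpool3_bwd(dY$x, cc$idx, cc$ncolIn), cc$sp, dY$n)
}

# ---- normalization --------------------------------------------------------

normParamsInit <- function(P, nm, C, batch = FALSE) {
  P[[paste0(nm, ".g")]] <- rep(1, C)
  P[[paste0(nm, ".be")]] <- numeric(C)
  if (batch) {
    P[[paste0(nm, ".rm")]] <- numeric(C)
    P[[paste0(nm, ".rv")]] <- rep(1, C)
  }
  invisible(P)
}

blockStat <- function(m, cg, G, S, n) {
  # per-(group, sample) means of a C x (S*n) matrix
  rs <- rowsum(m, rep(seq_len(G), each = cg), reorder = FALSE)
  rs2 <- rowsum(matrix(rs, G * S, n), rep(seq_len(G), times = S),
                reorder = FALSE)
  rs2 / (cg * S)
}

expandBlock <- function(m, cg, S, n) {
  # G x n matrix -> C x (S*n)
  m[rep(seq_len(nrow(m)), each = cg), rep(seq_len(n), each = S),
    drop = FALSE]
}

gnFwd <- function(P, nm, tin, groups = 4L, cache = NULL, eps = 1e-5) {
  g <- P[[paste0(nm, ".g")]]; be <- P[[paste0(nm, ".be")]]
  C <- nrow(tin$x); S <- prod(tin$sp); n <- tin$n
  cg <- C %/% groups
  mu <- blockStat(tin$x, cg, groups, S, n)
  m2 <- blockStat(tin$x^2, cg, groups, S, n)
  istd <- 1 / sqrt(pmax(m2 - mu^2, 0) + eps)
  muF <- expandBlock(mu, cg, S, n)
  isF <- expandBlock(istd, cg, S, n)
  xhat <- (tin$x - muF) * isF
  y <- g * xhat + be
  if (!is.null(cache))
    cache[[nm]] <- list(xhat = xhat, isF = isF, cg = cg, groups = groups,
                        S = S, n = n)
  nnTensor(y, tin$sp, tin$n)
}

gnBwd <- function(P, G, nm, cache, dY) {
  g <- P[[paste0(nm, ".g")]]
  cc <- cache[[nm]]
  addGrad(G, paste0(nm, ".g"), rowSums(dY$x * cc$xhat))
  addGrad(G, paste0(nm, ".be"), rowSums(dY$x))
  dxh <- dY$x * g
  m1 <- expandBlock(blockStat(dxh, cc$cg, cc$groups, cc$S, cc$n),
                    cc$cg, cc$S, cc$n)
  m2 <- expandBlock(blockStat(dxh * cc$xhat, cc$cg, cc$groups, cc$S, cc$n),
                    cc$cg, cc$S, cc$n)
  nnTensor(cc$isF * (dxh - m1 - cc$xhat * m2), dY$sp, dY$n)
}

bnFwd <- function(P, nm, tin, train = FALSE, cache = NULL, eps = 1e-5,
                  momentum = 0.1) {
  g <- P[[paste0(nm, ".g")]]; be <- P[[paste0(nm, ".be")]]
  if (train) {
    mu <- rowMeans(tin$x)
    v <- rowMeans(tin$x^2) - mu^2
    P[[paste0(nm, ".rm")]] <- (1 - momentum) * P[[paste0(nm, ".rm")]] +
      momentum * mu
    P[[paste0(nm, ".rv")]] <- (1 - momentum) * P[[paste0(nm, ".rv")]] +
      momentum * v
  } else {
    mu <- P[[paste0(nm, ".rm")]]
    v <- P[[paste0(nm, ".rv")]]
  }
  istd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- (tin$x - mu) * istd
  y <- g * xhat + be
  if (!is.null(cache))
    cache[[nm]] <- list(xhat = xhat, istd = istd, train = train)
  nnTensor(y, tin$sp, tin$n)
}

bnBwd <- function(P, G, nm, cache, dY) {
  g <- P[[paste0(nm, ".g")]]
  cc <- cache[[nm]]
  addGrad(G, paste0(nm, ".g"), rowSums(dY$x * cc$xhat))
  addGrad(G, paste0(nm, ".be"), rowSums(dY$x))
  dxh <- dY$x * g
  if (cc$train) {
    dx <- cc$istd * (dxh - rowMeans(dxh) - cc$xhat * rowMeans(dxh * cc$xhat))
  } else {
    dx <- cc$istd * dxh
  }
  nnTensor(dx, dY$sp, dY$n)
}

# ---- activations ----------------------------------------------------------

reluFwd <- function(nm, tin, cache = NULL) {
  y <- pmax(tin$x, 0)
  if (!is.null(cache)) cache[[nm]] <- list(mask = tin$x > 0)
  nnTensor(y, tin$sp, tin$n)
}

reluBwd <- function(nm, cache, dY) {
  nnTensor(dY$x * cache[[nm]]$mask, dY$sp, dY$n)
}

sigmoidMat <- function(z) 1 / (1 + exp(-z))

# ---- add / concat / gap ---------------------------------------------------

addGrad <- function(G, nm, val) {
  cur <- G[[nm]]
  G[[nm]] <- if (is.null(cur)) val else cur + val
  invisible(G)
}

concatFwd <- function(a, b) {
  nnTensor(rbind(a$x, b$x), a$sp, a$n)
}

concatBwd <- function(dY, nA) {
  list(nnTensor(dY$x[seq_len(nA), , drop = FALSE], dY$sp, dY$n),
       nnTensor(dY$x[-seq_len(nA), , drop = FALSE], dY$sp, dY$n))
}

gapFwd <- function(tin) {
  C <- nrow(tin$x); S <- prod(tin$sp)
  y <- vapply(seq_len(tin$n), function(b)
    rowMeans(tin$x[, ((b - 1) * S + 1):(b * S), drop = FALSE]),
    numeric(C))
  matrix(y, nrow = C)     # C x n
}

gapBwd <- function(dy, sp, n) {
  S <- prod(sp)
  nnTensor(dy[, rep(seq_len(n), each = S), drop = FALSE] / S, sp, n)
}

# ---- fully connected ------------------------------------------------------

fcParamsInit <- function(P, nm, nin, nout) {
  P[[paste0(nm, ".w")]] <- heInit(nout, nin)
  P[[paste0(nm, ".b")]] <- numeric(nout)
  invisible(P)
}

fcFwd <- function(P, nm, x, cache = NULL) {
  y <- P[[paste0(nm, ".w")]] %*% x + P[[paste0(nm, ".b")]]
  if (!is.null(cache)) cache[[nm]] <- list(xin = x)
  y
}

fcBwd <- function(P, G, nm, cache, dy) {
  addGrad(G, paste0(nm, ".w"), tcrossprod(dy, cache[[nm]]$xin))
  addGrad(G, paste0(nm, ".b"), rowSums(dy))
  crossprod(P[[paste0(nm, ".w")]], dy)
}

# ---- optimizer ------------------------------------------------------------

adamInit <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list(); st$v <- list()
  st
}

# Adam with classic L2 weight decay folded into the gradient.
adamStep <- function(P, G, st, names, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t; b2t <- 1 - beta2^st$t
  for (nm in names) {
    g <- G[[nm]]
    if (is.null(g)) next
    if (weightDecay > 0) g <- g + weightDecay * P[[nm]]
    m <- st$m[[nm]]; v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    st$m[[nm]] <- m; st$v[[nm]] <- v
    P[[nm]] <- P[[nm]] - lr * (m / b1t) / (sqrt(v / b2t) + eps)
  }
  invisible(P)
}

newParamEnv <- function() new.env(parent = emptyenv())
newGradEnv <- function() new.env(parent = emptyenv())

paramSnapshot <- function(P, names = ls(P)) {
  setNames(lapply(names, function(nm) P[[nm]]), names)
}
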