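# Finite-difference gradient checks of the network engine. The analytic
# backward passes must agree with central differences on randomly probed
# parameters; this covers conv, transposed conv, pooling, group/batch
# norm, the residual U-Net wiring and the focal loss gradient.

relErr <- function(a, b) abs(a - b) / pmax(1e-7, abs(a) + abs(b))

test_that("BL-UNet backward matches finite differences", {
  cfg <- polartrack:::netConfig(c(8, 8, 8), baseChannels = 4)
  net <- buildBlUnet(cfg, seed = 3)
  withr::with_seed(51, {
    x <- array(rnorm(512), c(8, 8, 8))
    y <- matrix(rbinom(512, 1, 0.3), nrow = 1)
  })
  tin <- polartrack:::arrayToTensor(x)
  lossOf <- function() {
    out <- polartrack:::blFwd(net, tin)
    focalLoss(out$probs$x, y)
  }
  cache <- new.env(parent = emptyenv())
  out <- polartrack:::blFwd(net, tin, cache = cache)
  p <- out$probs$x
  dp <- polartrack:::focalLossGrad(p, y)
  dLogits <- polartrack:::nnTensor(dp * p * (1 - p), out$probs$sp,
                                   out$probs$n)
  G <- polartrack:::newGradEnv()
  polartrack:::blBwd(net, G, cache, dLogits)
  P <- net$P
  withr::with_seed(52, {
    probes <- sample(ls(P), 15)
    for (nm in probes) {
      w <- P[[nm]]
      i <- sample(length(w), 1)
      h <- 1e-5
      P[[nm]][i] <- w[i] + h; lp <- lossOf()
      P[[nm]][i] <- w[i] - h; lm <- lossOf()
      P[[nm]][i] <- w[i]
      num <- (lp - lm) / (2 * h)
      ana <- if (is.null(G[[nm]])) 0 else G[[nm]][i]
      if (abs(num) + abs(ana) > 1e-7)
        expect_lt(relErr(num, ana), 1e-4, label = nm)
    }
  })
})

test_that("polar head backward matches finite differences", {
  cfg <- polartrack:::netConfig(c(8, 8, 8), baseChannels = 4)
  pn <- buildPolarUnet(buildBlUnet(cfg, seed = 3), seed = 4)
  n <- 3
  withr::with_seed(53, {
    vois <- lapply(1:n, function(i) array(rnorm(512), c(8, 8, 8)))
    rel <- matrix(runif(3 * n), 3, n)
    tAng <- runif(n, -1, 1); tRad <- runif(n)
    aOne <- matrix(0, 3, n); aOne[cbind(sample(1:3, n, TRUE), 1:n)] <- 1
  })
  tin <- polartrack:::arrayToTensor(vois)
  snap <- polartrack:::paramSnapshot(pn$P)
  resetBN <- function()
    for (nm in grep("\\.(rm|rv)$", names(snap), value = TRUE))
      pn$P[[nm]] <- snap[[nm]]
  lossOf <- function() {
    out <- polartrack:::polarFwd(pn, tin, rel, train = TRUE)
    pt <- colSums(out$actionProbs * aOne)
    focalLoss(pt, rep(1, n)) + l2Loss(out$angle, tAng) +
      l2Loss(out$radius, tRad)
  }
  cache <- new.env(parent = emptyenv())
  out <- polartrack:::polarFwd(pn, tin, rel, cache = cache, train = TRUE)
  pt <- colSums(out$actionProbs * aOne)
  eps <- 1e-7; al <- 0.25; ga <- 2
  ptc <- pmin(pmax(pt, eps), 1 - eps)
  g <- al * (ga * (1 - ptc)^(ga - 1) * log(ptc) - (1 - ptc)^ga / ptc) / n
  dzc <- sweep(aOne - out$actionProbs, 2, pt * g, "*")
  dza <- (2 * (out$angle - tAng) / n) * (1 - out$angle^2)
  dzr <- (2 * (out$radius - tRad) / n) * out$radius * (1 - out$radius)
  G <- polartrack:::newGradEnv()
  polartrack:::polarBwd(pn, G, cache, dza, dzr, dzc)
  withr::with_seed(54, {
    probes <- sample(grep("\\.(rm|rv)$", pn$trainable, value = TRUE,
                          invert = TRUE), 12)
    for (nm in probes) {
      w <- pn$P[[nm]]
      i <- sample(length(w), 1)
      h <- 1e-5
      pn$P[[nm]][i] <- w[i] + h; resetBN(); lp <- lossOf()
      pn$P[[nm]][i] <- w[i] - h; resetBN(); lm <- lossOf()
      pn$P[[nm]][i] <- w[i]; resetBN()
      num <- (lp - lm) / (2 * h)
      ana <- if (is.null(G[[nm]])) 0 else G[[nm]][i]
      if (abs(num) + abs(ana) > 1e-6)
        expect_lt(relErr(num, ana), 1e-3, label = nm)
    }
  })
})

test_that("im2col/col2im are exact adjoints", {
  withr::with_seed(55, {
    dims <- c(6L, 7L, 5L); n <- 2L; C <- 3L
    x <- matrix(rnorm(C * prod(dims) * n), C)
    k <- rep(3L, 3); s <- c(1L, 1L, 1L); p <- rep(1L, 3)
    cols <- polartrack:::im2col3(x, dims, n, k, s, p)
    u <- matrix(rnorm(length(cols)), nrow(cols))
    lhs <- sum(cols * u)
    rhs <- sum(x * polartrack:::col2im3(u, C, dims, n, k, s, p))
    expect_equal(lhs, rhs, tolerance = 1e-10)
    # strided geometry (as used by transposed convolutions)
    s2 <- c(2L, 2L, 2L)
    dims2 <- c(8L, 8L, 8L)
    x2 <- matrix(rnorm(C * prod(dims2) * n), C)
    cols2 <- polartrack:::im2col3(x2, dims2, n, k, s2, p)
    u2 <- matrix(rnorm(length(cols2)), nrow(cols2))
    expect_equal(sum(cols2 * u2),
                 sum(x2 * polartrack:::col2im3(u2, C, dims2, n, k, s2, p)),
                 tolerance = 1e-10)
  })
})

test_that("chunked inference convolution equals the one-shot path", {
  cfg <- polartrack:::netConfig(c(16, 16, 8), baseChannels = 4)
  net <- buildBlUnet(cfg, seed = 6)
  withr::with_seed(56, x <- array(rnorm(16 * 16 * 8), c(8, 16, 16)))
  tin <- polartrack:::arrayToTensor(x)
  full <- polartrack:::convFwd(net$P, "stem.c1", tin)
  chunked <- polartrack:::convFwd(net$P, "stem.c1", tin, chunkCols = 500)
  expect_equal(chunked$x, full$x, tolerance = 1e-12)
})

test_that("focal loss matches closed forms and reduces to cross-entropy", {
  p <- c(0.2, 0.7, 0.9); y <- c(0, 1, 1)
  ce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focalLoss(p, y, alpha = 0.5, gamma = 0), 0.5 * ce,
               tolerance = 1e-12)
  # y = 1, p = 0.5, alpha 0.25, gamma 2: 0.25 * 0.25 * ln 2
  expect_equal(focalLoss(0.5, 1), 0.25 * 0.25 * log(2), tolerance = 1e-12)
  expect_equal(focalLoss(0.5, 1), 0.04332, tolerance = 1e-4)
  # p_t -> 1 drives the loss to 0; clamping keeps it finite at p = 0/1
  expect_lt(focalLoss(1 - 1e-9, 1), 1e-12)
  expect_true(is.finite(focalLoss(c(0, 1), c(1, 0))))
  # focal never exceeds the alpha-weighted cross-entropy
  withr::with_seed(57, {
    p <- runif(100, 0.01, 0.99); y <- rbinom(100, 1, 0.5)
    at <- ifelse(y == 1, 0.25, 0.75)
    cew <- mean(-at * log(ifelse(y == 1, p, 1 - p)))
    expect_lte(focalLoss(p, y), cew)
  })
  # gradient check
  withr::with_seed(58, {
    p <- runif(20, 0.05, 0.95); y <- rbinom(20, 1, 0.4)
    g <- polartrack:::focalLossGrad(p, y)
    for (i in c(1, 7, 13)) {
      h <- 1e-6
      pp <- p; pp[i] <- p[i] + h; pm <- p; pm[i] <- p[i] - h
      num <- (focalLoss(pp, y) - focalLoss(pm, y)) / (2 * h)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  })
})

test_that("l2 loss matches its examples", {
  expect_equal(l2Loss(c(1, 2), c(1, 2)), 0)
  expect_equal(l2Loss(c(2, 3), c(1, 2)), 1)
  expect_equal(l2Loss(c(0, 1), c(1, 0)), 1)
})
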