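# Synthetic head phantoms: a noisy soft-tissue background inside a skull
# shell, a smooth cranio-caudally ascending brainstem path, a contrast-
# filled artery along the path (CTA channel) with a hyperdense occluding
# thrombus segment (NCCT channel), and hyperdense distractor blobs away
# from the path. Every case carries the full reference annotation set, so
# the tracker, trainers and evaluation protocol are exercisable without
# clinical data.

#' Phantom generation parameters
#'
#' Defaults emulate the study conditions the pipeline is meant for: soft
#' tissue near 35 HU (the NCCT window centre), thrombus at 60 HU (hyperdense
#' artery sign range), CTA lumen at 300 HU (the CTA window centre, which the
#' \[-100, 200\] HU clip saturates exactly as it would clinically), and
#' per-case thrombus volumes drawn from a log-normal with median 0.15 mL
#' and log-sd 1.15, matching a reported cohort median (IQR) of 0.15
#' (0.07-0.34) mL.
#'
#' @param shape volume shape (Z, Y, X) in voxels, each at least 16.
#' @param spacing voxel spacing (sz, sy, sx) in mm.
#' @param thrombusMedianMl median of the log-normal thrombus volume (mL).
#' @param thrombusLogSigma log-scale sd of the thrombus volume.
#' @param locationCategory one of "VA", "BA", "VA+BA", "BA+PCA",
#'   "VA+BA+PCA", "PCA", "none" - the longitudinal section of the path that
#'   carries the thrombus ("none" gives an empty mask).
#' @param nDistractors number of hyperdense distractor blobs.
#' @param noiseSd Gaussian noise sd in HU.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param tissueHu,thrombusHu,lumenHu,skullHu intensities in HU.
#' @param arteryRadiusMm in-plane artery radius in mm.
#' @param pathWander maximal sinusoidal path amplitude (voxels).
#' @param distractorMinDist minimal in-plane distance (voxels) between a
#'   distractor centre and the same-slice path point.
#' @return A list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(shape = c(64L, 96L, 96L), spacing = c(2, 0.5, 0.5),
                        thrombusMedianMl = 0.15, thrombusLogSigma = 1.15,
                        locationCategory = "BA", nDistractors = 3L,
                        noiseSd = 5, seed = 1L, tissueHu = 35,
                        thrombusHu = 60, lumenHu = 300, skullHu = 700,
                        arteryRadiusMm = 2, pathWander = 8,
                        distractorMinDist = 20) {
  if (any(shape < 16)) stop("phantomSpec: shape components must be >= 16")
  if (thrombusMedianMl <= 0) stop("phantomSpec: thrombusMedianMl must be > 0")
  if (noiseSd < 0) stop("phantomSpec: noiseSd must be >= 0")
  cats <- c("VA", "BA", "VA+BA", "BA+PCA", "VA+BA+PCA", "PCA", "none")
  locationCategory <- match.arg(locationCategory, cats)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 thrombusMedianMl = thrombusMedianMl,
                 thrombusLogSigma = thrombusLogSigma,
                 locationCategory = locationCategory,
                 nDistractors = as.integer(nDistractors), noiseSd = noiseSd,
                 seed = as.integer(seed), tissueHu = tissueHu,
                 thrombusHu = thrombusHu, lumenHu = lumenHu,
                 skullHu = skullHu, arteryRadiusMm = arteryRadiusMm,
                 pathWander = pathWander,
                 distractorMinDist = distractorMinDist),
            class = "PhantomSpec")
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample thrombus volumes from the cohort size distribution
#'
#' Log-normal draws with the given median and log-scale sd. The default
#' log-sd 1.15 puts the theoretical quartiles at
#' `median * exp(±0.6745 * 1.15)`, i.e. near 0.07 and 0.33 mL for the
#' default median of 0.15 mL.
#'
#' @param n number of draws (uses the current RNG state).
#' @param medianMl distribution median in mL, > 0.
#' @param logSigma log-scale standard deviation; 0 gives a point mass at
#'   `medianMl`.
#' @return Numeric vector of volumes in mL.
#' @export
sampleThrombusVolume <- function(n = 1L, medianMl = 0.15, logSigma = 1.15) {
  if (medianMl <= 0) stop("sampleThrombusVolume: medianMl must be > 0")
  rlnorm(n, meanlog = log(medianMl), sdlog = logSigma)
}

# Longitudinal path sections by category: VA = caudal, BA = middle,
# PCA = cranial third of the annotated path.
categorySections <- function(category, nPath) {
  thirds <- round(seq(0, nPath, length.out = 4))
  sec <- list(VA = (thirds[1] + 1):thirds[2],
              BA = (thirds[2] + 1):thirds[3],
              PCA = (thirds[3] + 1):thirds[4])
  parts <- strsplit(category, "+", fixed = TRUE)[[1]]
  sort(unique(unlist(sec[parts])))
}

#' Generate one synthetic head phantom
#'
#' Deterministic given `spec$seed`. The thrombus axial extent and in-plane
#' radius are solved so that the rasterized foreground volume matches the
#' sampled target volume up to discretization error.
#'
#' @param spec a [phantomSpec()].
#' @return A [PhantomCase-class].
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  withSeed(spec$seed, generatePhantomImpl(spec))
}

generatePhantomImpl <- function(spec) {
  Z <- spec$shape[1]; Y <- spec$shape[2]; X <- spec$shape[3]
  sz <- spec$spacing[1]; sy <- spec$spacing[2]; sx <- spec$spacing[3]
  yc <- (Y + 1) / 2; xc <- (X + 1) / 2
  rowg <- matrix(seq_len(Y), Y, X)
  colg <- matrix(seq_len(X), Y, X, byrow = TRUE)

  ncct <- array(spec$tissueHu + rnorm(Z * Y * X, 0, spec$noiseSd), c(Z, Y, X))
  cta <- array(spec$tissueHu + rnorm(Z * Y * X, 0, spec$noiseSd), c(Z, Y, X))

  # head outline: in-plane ellipse; air outside, skull shell on upper slices
  rrel <- sqrt(((rowg - yc) / (0.46 * Y))^2 + ((colg - xc) / (0.46 * X))^2)
  airIdx <- which(rrel > 1)
  shellIdx <- which(rrel > 0.93 & rrel <= 1)
  skullZlo <- as.integer(ceiling(0.25 * Z))
  for (z in seq_len(Z)) {
    sl <- ncct[z, , ]; sl[airIdx] <- -1000
    sc <- cta[z, , ]; sc[airIdx] <- -1000
    if (z >= skullZlo) { sl[shellIdx] <- spec$skullHu
                         sc[shellIdx] <- spec$skullHu }
    ncct[z, , ] <- sl; cta[z, , ] <- sc
  }

  # brainstem path: sinusoidal in-plane wander around the slice centre
  zMaxPath <- as.integer(round(0.8 * Z))
  zs <- seq_len(zMaxPath)
  amp <- runif(2, 2, spec$pathWander)
  freq <- runif(2, 0.5, 1.5)
  pha <- runif(2, 0, 2 * pi)
  off <- runif(2, -4, 4)
  prow <- yc + off[1] + amp[1] * sin(2 * pi * freq[1] * zs / Z + pha[1])
  pcol <- xc + off[2] + amp[2] * sin(2 * pi * freq[2] * zs / Z + pha[2])
  path <- ReferencePath(cbind(prow, pcol), zMin = 1L)

  # thrombus extent and radius solved against the sampled target volume
  mask <- array(0, c(Z, Y, X))
  targetMl <- 0
  if (spec$locationCategory != "none") {
    section <- categorySections(spec$locationCategory, zMaxPath)
    voxVol <- sz * sy * sx            # mm^3
    rMaxMm <- 6   # large thrombi may distend well beyond the lumen
    targetMl <- sampleThrombusVolume(1, spec$thrombusMedianMl,
                                     spec$thrombusLogSigma)
    kTarget <- max(1L, as.integer(round(targetMl * 1000 / voxVol)))
    nSlices <- min(length(section),
                   max(1L, as.integer(round(
                     targetMl * 1000 / (pi * spec$arteryRadiusMm^2) / sz))))
    # capacity check at maximal radius and extent
    slArea <- sum((((rowg - yc) * sy)^2 + ((colg - xc) * sx)^2) <= rMaxMm^2)
    if (kTarget > slArea * length(section))
      stop("generatePhantom: thrombus volume ", signif(targetMl, 3),
           " mL cannot fit section '", spec$locationCategory,
           "' (capacity ", signif(slArea * length(section) * voxVol / 1000, 3),
           " mL)")
    nSlices <- max(nSlices, as.integer(ceiling(kTarget / slArea)))
    start <- section[1] + sample.int(length(section) - nSlices + 1L, 1L) - 1L
    extent <- start:(start + nSlices - 1L)
    # pool in-plane distances (mm) to the same-slice path point
    dists <- unlist(lapply(extent, function(z) {
      d2 <- ((rowg - prow[z]) * sy)^2 + ((colg - pcol[z]) * sx)^2
      d2[d2 <= rMaxMm^2]
    }))
    dists <- sqrt(sort(dists))
    rT <- dists[min(kTarget, length(dists))] + 1e-9
    for (z in extent) {
      d2 <- ((rowg - prow[z]) * sy)^2 + ((colg - pcol[z]) * sx)^2
      hit <- d2 <= rT^2
      sl <- mask[z, , ]; sl[hit] <- 1; mask[z, , ] <- sl
      nc <- ncct[z, , ]; nc[hit] <- spec$thrombusHu + rnorm(sum(hit), 0,
                                                            spec$noiseSd / 2)
      ncct[z, , ] <- nc
    }
  } else {
    extent <- integer(0)
  }

  # artery along the path on CTA: contrast-filled lumen, except over the
  # thrombus extent (filling defect)
  rAvox2 <- (spec$arteryRadiusMm / sy)^2
  for (z in zs) {
    if (z %in% extent) next
    d2 <- (rowg - prow[z])^2 + (colg - pcol[z])^2
    hit <- d2 <= rAvox2
    sc <- cta[z, , ]; sc[hit] <- spec$lumenHu + rnorm(sum(hit), 0,
                                                      spec$noiseSd / 2)
    cta[z, , ] <- sc
  }

  # hyperdense distractors away from the path (NCCT channel)
  if (spec$nDistractors > 0) for (i in seq_len(spec$nDistractors)) {
    radMm <- runif(1, 0.8, 1.8)
    hu <- runif(1, 60, 200)
    ok <- FALSE
    for (try in 1:100) {
      zd <- sample.int(zMaxPath, 1L)
      crow <- runif(1, yc - 0.38 * Y, yc + 0.38 * Y)
      ccol <- runif(1, xc - 0.38 * X, xc + 0.38 * X)
      zSpan <- max(1L, zd - as.integer(radMm / sz)):
        min(zMaxPath, zd + as.integer(radMm / sz))
      dPath <- sqrt((crow - prow[zSpan])^2 + (ccol - pcol[zSpan])^2)
      inHead <- sqrt(((crow - yc) / (0.46 * Y))^2 +
                       ((ccol - xc) / (0.46 * X))^2) < 0.85
      if (inHead && all(dPath >= spec$distractorMinDist)) { ok <- TRUE; break }
    }
    if (!ok) next   # no admissible position; place fewer distractors
    for (z in zSpan) {
      dz <- (z - zd) * sz
      r2 <- radMm^2 - dz^2
      if (r2 <= 0) next
      d2 <- ((rowg - crow) * sy)^2 + ((colg - ccol) * sx)^2
      hit <- d2 <= r2
      nc <- ncct[z, , ]; nc[hit] <- hu
      ncct[z, , ] <- nc
    }
  }

  msk <- SegmentationMask(mask, spacing = spec$spacing)
  new("PhantomCase",
      ncct = ImageVolume(ncct, spacing = spec$spacing),
      cta = ImageVolume(cta, spacing = spec$spacing),
      thrombus = msk, path = path,
      meta = list(category = spec$locationCategory,
                  true_volume_ml = targetMl,
                  rasterized_volume_ml = volumeMl(msk),
                  seed = spec$seed))
}

#' Default occlusion-location mixture
#'
#' Category probabilities proportional to the located strata of the cohort
#' the generator emulates (VA 9, BA 37, VA+BA 22, BA+PCA 49, VA+BA+PCA 8,
#' PCA 19), scaled so that a scan shows no visible thrombus with
#' probability 2/187.
#'
#' @return Named probability vector over the seven location categories.
#' @export
defaultLocationMix <- function() {
  counts <- c(VA = 9, BA = 37, `VA+BA` = 22, `BA+PCA` = 49,
              `VA+BA+PCA` = 8, PCA = 19)
  pNone <- 2 / 187
  c(counts / sum(counts) * (1 - pNone), none = pNone)
}

#' Sample location-category labels
#'
#' @param n number of labels.
#' @param mix named probability vector (must sum to 1).
#' @return Character vector of length `n`.
#' @export
sampleLocationCategories <- function(n, mix = defaultLocationMix()) {
  if (abs(sum(mix) - 1) > 1e-8)
    stop("sampleLocationCategories: probabilities must sum to 1")
  if (n == 0L) return(character(0))
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Generate a stratified phantom cohort
#'
#' Per-case seeds are derived from the master seed (`seed + case index`),
#' so cohorts are reproducible with independent cases. A case whose sampled
#' thrombus volume cannot fit its arterial section is resampled with a
#' deterministically derived retry seed.
#'
#' @param n number of cases.
#' @param spec template [phantomSpec()]; per-case seed and category are
#'   overridden.
#' @param locationMix named category probability vector.
#' @param seed master seed.
#' @param summarize optional function applied to each [PhantomCase-class];
#'   when given, its value is stored instead of the case (keeps large
#'   cohorts in memory-friendly form).
#' @return List of cases (or summaries), with the category labels as
#'   attribute `"categories"`.
#' @export
generateCohort <- function(n, spec = phantomSpec(),
                           locationMix = defaultLocationMix(), seed = 1L,
                           summarize = NULL) {
  cats <- withSeed(seed, sampleLocationCategories(n, locationMix))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    csSpec <- spec
    csSpec$locationCategory <- cats[i]
    csSpec$seed <- as.integer(seed + i)
    cs <- NULL
    for (attempt in 0:4) {
      csSpec$seed <- as.integer(seed + i + attempt * 1000003L)
      cs <- tryCatch(generatePhantom(csSpec), error = function(e) NULL)
      if (!is.null(cs)) break
    }
    if (is.null(cs))
      stop("generateCohort: failed to generate case ", i)
    out[[i]] <- if (is.null(summarize)) cs else summarize(cs)
  }
  attr(out, "categories") <- cats
  out
}

# ---- path sidecar JSON ----------------------------------------------------

#' Write / read the reference-path sidecar JSON
#'
#' Format: `{"z_min": ..., "z_max": ..., "points": {"<z>": [row, col], ...}}`
#' with 1-based slice indices.
#'
#' @param path a [ReferencePath-class].
#' @param file output path.
#' @return `file` (write) or a [ReferencePath-class] (read).
#' @export
writePathJson <- function(path, file) {
  zr <- zRange(path)
  pts <- lapply(seq_len(nrow(path@points)),
                function(i) unname(path@points[i, ]))
  names(pts) <- as.character(seq(zr[1], zr[2]))
  jsonlite::write_json(list(z_min = zr[1], z_max = zr[2], points = pts),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writePathJson
#' @export
readPathJson <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  zmin <- as.integer(obj$z_min); zmax <- as.integer(obj$z_max)
  pts <- t(vapply(as.character(seq(zmin, zmax)),
                  function(k) as.numeric(obj$points[[k]]), numeric(2)))
  ReferencePath(pts, zMin = zmin)
}

#' Write a phantom case to disk
#'
#' Writes `<prefix>_ncct.nii.gz`, `<prefix>_cta.nii.gz`,
#' `<prefix>_thrombus.nii.gz` and `<prefix>_path.json` into `dir`.
#'
#' @param case a [PhantomCase-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the written paths.
#' @export
writePhantomCase <- function(case, dir, prefix = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(s) file.path(dir, paste0(prefix, "_", s))
  writeVolume(case@ncct, p("ncct.nii.gz"))
  writeVolume(case@cta, p("cta.nii.gz"))
  writeVolume(case@thrombus, p("thrombus.nii.gz"))
  writePathJson(case@path, p("path.json"))
  c(ncct = p("ncct.nii.gz"), cta = p("cta.nii.gz"),
    thrombus = p("thrombus.nii.gz"), path = p("path.json"))
}
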