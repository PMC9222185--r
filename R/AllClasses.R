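#' @useDynLib polartrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rlnorm qlnorm sd var median quantile
#'   shapiro.test t.test wilcox.test pf qf pnorm setNames plnorm
NULL

#' ImageVolume: a 3D scalar image with voxel spacing
#'
#' Container for a CT-like scan (or a phantom). The voxel array is indexed
#' `[z, y, x]` with slice index `z = 1` the most caudal slice and `z`
#' increasing cranially; in-plane coordinates are `(row y, col x)`.
#' Spacing and origin are stored in millimetres in the same `(z, y, x)`
#' order.
#'
#' @slot voxels 3D numeric array indexed (z, y, x).
#' @slot spacing numeric length-3, voxel size in mm (sz, sy, sx), all > 0.
#' @slot origin numeric length-3, position of voxel (1,1,1) in mm (oz, oy, ox).
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(voxels = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "voxels must be finite")
  if (length(msg)) msg else TRUE
})

#' SegmentationMask: a binary mask aligned to an ImageVolume
#'
#' @slot voxels 3D array with values in \{0, 1\}.
#' @slot spacing numeric length-3 voxel size in mm (sz, sy, sx).
#' @export
setClass("SegmentationMask",
  representation(voxels = "array", spacing = "numeric"),
  prototype(voxels = array(0, c(1, 1, 1)), spacing = c(1, 1, 1)))

setValidity("SegmentationMask", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (!all(object@voxels %in% c(0, 1)))
    msg <- c(msg, "mask voxels must be 0 or 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' ReferencePath: one annotated in-plane point per axial slice
#'
#' The brainstem reference path: for every slice in `[zMin, zMax]` exactly
#' one `(row, col)` coordinate (1-based, possibly fractional after
#' augmentation).
#'
#' @slot points numeric matrix with columns `row`, `col`; row i corresponds
#'   to slice `zMin + i - 1`.
#' @slot zMin,zMax integer slice range (1-based, inclusive).
#' @export
setClass("ReferencePath",
  representation(points = "matrix", zMin = "integer", zMax = "integer"))

setValidity("ReferencePath", function(object) {
  msg <- character()
  n <- object@zMax - object@zMin + 1L
  if (object@zMin < 1L || object@zMax < object@zMin)
    msg <- c(msg, "need 1 <= zMin <= zMax")
  if (nrow(object@points) != n || ncol(object@points) != 2L)
    msg <- c(msg, "points must be a (zMax - zMin + 1) x 2 matrix")
  if (any(!is.finite(object@points)))
    msg <- c(msg, "path points must be finite")
  if (length(msg)) msg else TRUE
})

#' PhantomCase: one synthetic head case with all annotations
#'
#' @slot ncct,cta ImageVolume channels (raw HU).
#' @slot thrombus SegmentationMask reference segmentation.
#' @slot path ReferencePath brainstem path annotation.
#' @slot meta list: `category`, `true_volume_ml` (sampled target),
#'   `rasterized_volume_ml`, `seed`.
#' @export
setClass("PhantomCase",
  representation(ncct = "ImageVolume", cta = "ImageVolume",
                 thrombus = "SegmentationMask", path = "ReferencePath",
                 meta = "list"))

setValidity("PhantomCase", function(object) {
  msg <- character()
  d <- dim(object@ncct@voxels)
  if (!identical(d, dim(object@cta@voxels)) ||
      !identical(d, dim(object@thrombus@voxels)))
    msg <- c(msg, "ncct, cta and thrombus must share one shape")
  if (!isTRUE(all.equal(object@ncct@spacing, object@thrombus@spacing)))
    msg <- c(msg, "ncct and thrombus must share spacing")
  if (length(msg)) msg else TRUE
})

#' CCMatchResult: component-level localization bookkeeping for one case
#'
#' @slot refComponents,predComponents data.frames with columns `label`,
#'   `voxels`, `volume_ml`, `matched`.
#' @slot tpRef,tpPred,fp,fn integer counts; `tpPred + fp` equals the number
#'   of predicted components and `tpRef + fn` the number of reference
#'   components.
#' @export
setClass("CCMatchResult",
  representation(refComponents = "data.frame", predComponents = "data.frame",
                 tpRef = "integer", tpPred = "integer",
                 fp = "integer", fn = "integer"))

setValidity("CCMatchResult", function(object) {
  msg <- character()
  if (object@tpPred + object@fp != nrow(object@predComponents))
    msg <- c(msg, "tpPred + fp must equal number of predicted components")
  if (object@tpRef + object@fn != nrow(object@refComponents))
    msg <- c(msg, "tpRef + fn must equal number of reference components")
  if (length(msg)) msg else TRUE
})

# ---- constructors ---------------------------------------------------------

#' Create an ImageVolume
#'
#' @param voxels 3D numeric array indexed (z, y, x).
#' @param spacing voxel size in mm, (sz, sy, sx).
#' @param origin position of voxel (1,1,1) in mm, (oz, oy, ox).
#' @return An [ImageVolume-class] object.
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a SegmentationMask
#'
#' @param voxels 3D array coercible to \{0, 1\}; logical arrays are accepted.
#' @param spacing voxel size in mm, (sz, sy, sx).
#' @return A [SegmentationMask-class] object.
#' @export
SegmentationMask <- function(voxels, spacing = c(1, 1, 1)) {
  if (is.logical(voxels)) {
    d <- dim(voxels)
    voxels <- array(as.numeric(voxels), d)
  }
  new("SegmentationMask", voxels = voxels, spacing = as.numeric(spacing))
}

#' Create a ReferencePath
#'
#' @param points n x 2 matrix of (row, col) coordinates, one per slice.
#' @param zMin first annotated slice (1-based).
#' @return A [ReferencePath-class] object.
#' @export
ReferencePath <- function(points, zMin = 1L) {
  points <- as.matrix(points)
  colnames(points) <- c("row", "col")
  new("ReferencePath", points = points, zMin = as.integer(zMin),
      zMax = as.integer(zMin + nrow(points) - 1L))
}

# ---- generics and accessors ----------------------------------------------

#' @rdname ImageVolume-class
#' @param object,x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname ImageVolume-class
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)
#' @rdname SegmentationMask-class
#' @param x an object.
#' @export
setMethod("voxels", "SegmentationMask", function(x) x@voxels)

#' @rdname ImageVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname ImageVolume-class
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname SegmentationMask-class
#' @export
setMethod("spacing", "SegmentationMask", function(x) x@spacing)

#' @rdname ImageVolume-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname ImageVolume-class
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)

#' Path point lookup
#'
#' Returns the (row, col) coordinate of the reference path on slice `z`, or
#' `NULL` when `z` lies outside the annotated range.
#'
#' @param path a [ReferencePath-class].
#' @param z slice index (1-based).
#' @return Numeric length-2 `(row, col)` or `NULL`.
#' @export
pathPoint <- function(path, z) {
  if (z < path@zMin || z > path@zMax) return(NULL)
  path@points[z - path@zMin + 1L, ]
}

#' @rdname ReferencePath-class
#' @param x an object.
#' @export
setGeneric("zRange", function(x) standardGeneric("zRange"))
#' @rdname ReferencePath-class
#' @export
setMethod("zRange", "ReferencePath", function(x) c(x@zMin, x@zMax))

#' @rdname PhantomCase-class
#' @param x an object.
#' @export
setGeneric("caseMeta", function(x) standardGeneric("caseMeta"))
#' @rdname PhantomCase-class
#' @export
setMethod("caseMeta", "PhantomCase", function(x) x@meta)

# ---- show methods ---------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume %d x %d x %d (z,y,x), spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x "),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("SegmentationMask %d x %d x %d, %d foreground voxels (%.4g mL)\n",
              d[1], d[2], d[3], sum(object@voxels != 0), volumeMl(object)))
})

setMethod("show", "ReferencePath", function(object) {
  cat(sprintf("ReferencePath over slices %d..%d (%d points)\n",
              object@zMin, object@zMax, nrow(object@points)))
})

setMethod("show", "PhantomCase", function(object) {
  d <- dim(object@ncct@voxels)
  cat(sprintf("PhantomCase %d x %d x %d, category %s, thrombus %.3g mL (seed %s)\n",
              d[1], d[2], d[3], object@meta$category,
              object@meta$rasterized_volume_ml,
              format(object@meta$seed)))
})

setMethod("show", "CCMatchResult", function(object) {
  cat(sprintf("CCMatchResult: %d ref / %d pred components; TPref %d, TPpred %d, FP %d, FN %d\n",
              nrow(object@refComponents), nrow(object@predComponents),
              object@tpRef, object@tpPred, object@fp, object@fn))
})
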