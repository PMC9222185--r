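# Volume IO and Hounsfield-unit preprocessing.
#
# NIfTI files store arrays x-fastest; so does MetaImage raw data. The
# package convention is (z, y, x), so arrays and spacing/origin triples are
# reversed at the IO boundary and nowhere else.

metaTypeTable <- data.frame(
  met = c("MET_UCHAR", "MET_CHAR", "MET_SHORT", "MET_USHORT", "MET_INT",
          "MET_UINT", "MET_FLOAT", "MET_DOUBLE"),
  what = c("integer", "integer", "integer", "integer", "integer", "integer",
           "numeric", "numeric"),
  size = c(1L, 1L, 2L, 2L, 4L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE)

hasExt <- function(path, ext) {
  grepl(paste0("\\.(", ext, ")$"), path, ignore.case = TRUE)
}

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Reads `.nii`, `.nii.gz`, `.mha` or `.mhd` (+ raw) files into an
#' [ImageVolume-class]. The returned array is indexed `(z, y, x)` with
#' `z = 1` the most caudal slice; spacing and origin are reported in the
#' same order, in mm.
#'
#' @param path file path.
#' @return An [ImageVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("readVolume: file not found: ", path)
  if (hasExt(path, "nii|nii\\.gz")) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L) stop("readVolume: expected a 3D image, got ",
                              length(d), " dimensions")
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      stop("readVolume: missing or invalid voxel spacing in NIfTI header")
    h <- RNifti::niftiHeader(img)
    org <- c(h$qoffset_z, h$qoffset_y, h$qoffset_x)
    ImageVolume(aperm(as.array(img), c(3, 2, 1)),
                spacing = rev(pd[1:3]), origin = org)
  } else if (hasExt(path, "mha|mhd")) {
    readMetaImage(path)
  } else {
    stop("readVolume: unsupported file extension for ", path)
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' The file format follows the extension of `path`. Masks
#' ([SegmentationMask-class]) are written as unsigned 8-bit with values
#' \{0, 1\}; images as the floating-point type of the format.
#'
#' @param x an [ImageVolume-class] or [SegmentationMask-class].
#' @param path output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  isMask <- is(x, "SegmentationMask")
  vox <- voxels(x)
  sp <- spacing(x)
  org <- if (isMask) c(0, 0, 0) else origin(x)
  if (hasExt(path, "nii|nii\\.gz")) {
    arr <- aperm(vox, c(3, 2, 1))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(sp)
    h <- RNifti::niftiHeader(img)
    h$qoffset_x <- org[3]; h$qoffset_y <- org[2]; h$qoffset_z <- org[1]
    h$qform_code <- 1
    img <- RNifti::asNifti(arr, reference = h)
    RNifti::writeNifti(img, path,
                       datatype = if (isMask) "uint8" else "double")
  } else if (hasExt(path, "mha|mhd")) {
    writeMetaImage(vox, sp, org, path,
                   type = if (isMask) "MET_UCHAR" else "MET_DOUBLE")
  } else {
    stop("writeVolume: unsupported file extension for ", path)
  }
  invisible(path)
}

# Minimal MetaImage reader: uncompressed binary, scalar element types.
readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("readVolume: MetaImage header has no ElementDataFile entry")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("readVolume: malformed MetaImage header line: ",
                               line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!is.null(hdr$NDims) && as.integer(hdr$NDims) != 3L)
    stop("readVolume: expected a 3D image, NDims = ", hdr$NDims)
  if (identical(tolower(hdr$CompressedData), "true"))
    stop("readVolume: compressed MetaImage data is not supported")
  if (is.null(hdr$DimSize)) stop("readVolume: MetaImage header lacks DimSize")
  dimXYZ <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dimXYZ) != 3L) stop("readVolume: expected a 3D image")
  if (is.null(hdr$ElementSpacing))
    stop("readVolume: MetaImage header lacks ElementSpacing")
  spXYZ <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  if (any(!is.finite(spXYZ)) || any(spXYZ <= 0))
    stop("readVolume: invalid ElementSpacing")
  orgXYZ <- if (is.null(hdr$Offset)) c(0, 0, 0) else
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  ty <- metaTypeTable[metaTypeTable$met == hdr$ElementType, ]
  if (nrow(ty) != 1L)
    stop("readVolume: unsupported ElementType ", hdr$ElementType)
  bigend <- identical(tolower(hdr$BinaryDataByteOrderMSB), "true") ||
    identical(tolower(hdr$ElementByteOrderMSB), "true")
  nvox <- prod(dimXYZ)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    dat <- readBin(con, ty$what, n = nvox, size = ty$size,
                   signed = ty$signed || ty$size > 2,
                   endian = if (bigend) "big" else "little")
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawPath))
      stop("readVolume: raw data file not found: ", rawPath)
    rcon <- file(rawPath, "rb")
    on.exit(close(rcon), add = TRUE)
    dat <- readBin(rcon, ty$what, n = nvox, size = ty$size,
                   signed = ty$signed || ty$size > 2,
                   endian = if (bigend) "big" else "little")
  }
  if (length(dat) != nvox)
    stop("readVolume: truncated MetaImage data (", length(dat), " of ",
         nvox, " voxels)")
  arr <- aperm(array(as.numeric(dat), dimXYZ), c(3, 2, 1))
  ImageVolume(arr, spacing = rev(spXYZ), origin = rev(orgXYZ))
}

writeMetaImage <- function(vox, sp, org, path, type = "MET_DOUBLE") {
  ty <- metaTypeTable[metaTypeTable$met == type, ]
  stopifnot(nrow(ty) == 1L)
  d <- dim(vox)
  local <- hasExt(path, "mha")
  dataFile <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(rev(d), collapse = " ")),
    paste("ElementSpacing =", paste(format(rev(sp), trim = TRUE),
                                    collapse = " ")),
    paste("Offset =", paste(format(rev(org), trim = TRUE), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", dataFile))
  dat <- as.vector(aperm(vox, c(3, 2, 1)))
  if (ty$what == "integer") dat <- as.integer(round(dat))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local) {
    writeBin(dat, con, size = ty$size, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), dataFile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(dat, rcon, size = ty$size, endian = "little")
  }
  invisible(path)
}

#' Crop a scan to the region below the top of the skull
#'
#' Locates the most cranial slice containing bone (any voxel above
#' `boneHu`) and keeps that slice plus everything down to `extentMm` below
#' it; slices above the skull top and more than `extentMm` below it are
#' discarded. If no voxel exceeds the bone threshold, the volume is
#' returned unchanged with attribute `cropWarning = TRUE` and a warning.
#'
#' @param v an [ImageVolume-class] in raw HU (pre-normalization).
#' @param extentMm physical extent to retain below the skull top (mm).
#' @param boneHu bone detection threshold in HU.
#' @return An [ImageVolume-class]; possibly the input with a warning flag.
#' @export
cropBelowSkull <- function(v, extentMm = 250, boneHu = 300) {
  vox <- voxels(v)
  sz <- spacing(v)[1]
  boneSlices <- which(apply(vox > boneHu, 1, any))
  if (length(boneSlices) == 0L) {
    warning("cropBelowSkull: no voxel above ", boneHu,
            " HU; volume returned unchanged")
    attr(v, "cropWarning") <- TRUE
    return(v)
  }
  zTop <- max(boneSlices)
  zLo <- max(1L, zTop - as.integer(floor(extentMm / sz)))
  out <- ImageVolume(vox[zLo:zTop, , , drop = FALSE], spacing = spacing(v),
                     origin = origin(v) + c((zLo - 1L) * sz, 0, 0))
  attr(out, "cropWarning") <- FALSE
  out
}

#' Clip HU values and normalize to the unit symmetric range
#'
#' Each voxel `x` maps to `2 * (clamp(x, lo, hi) - lo) / (hi - lo) - 1`, so
#' `lo` maps to -1 and `hi` to +1.
#'
#' @param v an [ImageVolume-class].
#' @param lo,hi clip bounds in HU; `hi` must exceed `lo`.
#' @return An [ImageVolume-class] with voxels in `[-1, 1]`.
#' @export
clipNormalize <- function(v, lo = -100, hi = 200) {
  if (hi <= lo) stop("clipNormalize: need hi > lo")
  vox <- voxels(v)
  vox <- pmin(pmax(vox, lo), hi)
  ImageVolume(2 * (vox - lo) / (hi - lo) - 1, spacing = spacing(v),
              origin = origin(v))
}

#' Mask volume in millilitres
#'
#' Foreground voxel count times the voxel volume (product of the three
#' spacing components), converted from cubic mm to mL.
#'
#' @param m a [SegmentationMask-class].
#' @return Volume in mL.
#' @export
volumeMl <- function(m) {
  sum(voxels(m) != 0) * prod(spacing(m)) / 1000
}
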