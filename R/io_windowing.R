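## Reading CT data, brain windowing, channel triplication and the downscaled
## generator input.

#' Apply clinical display windowing to a CT slice
#'
#' Maps the Hounsfield-unit interval of width `windowWidth` centred at
#' `windowLevel` linearly onto [0, 1] and clips outside it -- the standard
#' radiology window map. The defaults are the brain window WW = 80, WL = 40,
#' under which grey/white matter and early ischemic hypodensity occupy most
#' of the display range.
#'
#' @param slice a [CTSlice-class].
#' @param windowWidth window width in HU, must be positive (default 80).
#' @param windowLevel window level (centre) in HU (default 40).
#' @return a single-channel [WindowedImage-class].
#' @examples
#' s <- ctSlice(matrix(c(-50, 0, 40, 200), 2, 2))
#' imageValues(huWindow(s), drop = TRUE)  # 0, 0, 0.5, 1
#' @export
huWindow <- function(slice, windowWidth = 80, windowLevel = 40) {
  stopifnot(is(slice, "CTSlice"))
  if (length(windowWidth) != 1L || !is.finite(windowWidth) || windowWidth <= 0)
    stop("'windowWidth' must be a positive scalar")
  lo <- windowLevel - windowWidth / 2
  v <- .clip01((slice@hu - lo) / windowWidth)
  windowedImage(v)
}

#' Triplicate a single-channel image across three planes
#'
#' Duplicates the windowed plane into three identical channels. This is a
#' tensor-shape convention only (3-channel backbones); no chromatic
#' information is introduced and all filters act channel-wise.
#'
#' @param img a single-channel [WindowedImage-class].
#' @return a three-channel [WindowedImage-class]; a 3-channel input is
#'   returned unchanged with a warning.
#' @export
triplicateChannels <- function(img) {
  stopifnot(is(img, "WindowedImage"))
  if (numChannels(img) == 3L) {
    warning("image already has 3 channels; returning unchanged")
    return(img)
  }
  p <- img@values[, , 1L]
  new("WindowedImage", values = array(c(p, p, p), dim = c(dim(p), 3L)))
}

#' Downscale an image to the generator input size
#'
#' Bilinear resize with half-pixel-centred sampling to a square
#' `target` x `target` grid (default 128, the parameter generator's working
#' resolution). Bilinear interpolation is convex, so output intensities stay
#' within the input range.
#'
#' @param img a [WindowedImage-class].
#' @param target output side length in pixels, at least 8 (default 128).
#' @return a [WindowedImage-class] of size target x target.
#' @export
downscaleImage <- function(img, target = 128L) {
  stopifnot(is(img, "WindowedImage"))
  target <- as.integer(target)
  if (target < 8L) stop("'target' must be at least 8 pixels")
  planes <- lapply(.asPlaneList(img@values), .resizePlane,
                   outH = target, outW = target, method = "bilinear")
  v <- .fromPlaneList(planes)
  if (is.matrix(v)) v <- array(v, c(target, target, 1L))
  new("WindowedImage", values = v)
}

#' Read a CT volume as a list of slices
#'
#' Supports NIfTI volumes (`.nii` / `.nii.gz`, via RNifti, values taken as
#' Hounsfield units) and directories of 2-D NIfTI or CSV slice files.
#' Slices are returned ordered by `sliceIndex` (ascending acquisition order;
#' ties broken by filename).
#'
#' @param path a NIfTI file or a directory of per-slice files.
#' @return list of [CTSlice-class], ordered by slice index.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file or directory")
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(nii(\\.gz)?|csv)$", full.names = TRUE)
    if (length(files) == 0L) {
      warning("no slice files found in '", path, "'")
      return(list())
    }
    slices <- lapply(sort(files), .readSliceFile)
    idx <- order(vapply(slices, function(s) s@sliceIndex, integer(1)))
    return(slices[idx])
  }
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  spacing <- if (length(pd) >= 2) pd[1:2] else c(1, 1)
  thick <- if (length(pd) >= 3) pd[3] else 1
  lapply(seq_len(dim(arr)[3L]), function(i)
    ctSlice(arr[, , i], pixelSpacing = spacing, sliceThickness = thick,
            sliceIndex = i))
}

#' @keywords internal
.readSliceFile <- function(f) {
  if (grepl("\\.csv$", f)) {
    m <- as.matrix(utils::read.csv(f, header = FALSE))
    idx <- suppressWarnings(as.integer(gsub("\\D", "", basename(f))))
    if (is.na(idx)) idx <- 1L
    return(ctSlice(m, sliceIndex = idx))
  }
  img <- RNifti::readNifti(f)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  idx <- suppressWarnings(as.integer(gsub("\\D", "", basename(f))))
  if (is.na(idx)) idx <- 1L
  pd <- RNifti::pixdim(img)
  ctSlice(arr, pixelSpacing = if (length(pd) >= 2) pd[1:2] else c(1, 1),
          sliceThickness = if (length(pd) >= 3) pd[3] else 1, sliceIndex = idx)
}

#' Write a windowed image to an 8-bit grayscale PNG
#'
#' Values are quantised as round(v * 255); the round trip through
#' [readPngImage()] is therefore accurate to 1/255 per pixel.
#'
#' @param img a [WindowedImage-class] with values in [0, 1].
#' @param path output file path; the parent directory must exist.
#' @return the path, invisibly.
#' @export
writePngImage <- function(img, path) {
  stopifnot(is(img, "WindowedImage"))
  if (!dir.exists(dirname(path))) stop("directory '", dirname(path), "' does not exist")
  v <- imageValues(img, drop = TRUE)
  if (!is.matrix(v)) v <- v[, , 1L]  # identical planes: store one
  v <- round(.clip01(v) * 255) / 255
  png::writePNG(v, target = path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG as a WindowedImage
#' @param path PNG file path.
#' @return a single-channel [WindowedImage-class].
#' @export
readPngImage <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  windowedImage(v)
}

#' Write a label mask as an integer-coded PNG
#'
#' Encodes background/core/penumbra as the integer codes 0/1/2 stored in an
#' 8-bit grayscale PNG (value = code/255).
#'
#' @param coreMask,penumbraMask logical matrices, disjoint.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMaskPng <- function(coreMask, penumbraMask, path) {
  stopifnot(!any(coreMask & penumbraMask))
  code <- matrix(0L, nrow(coreMask), ncol(coreMask))
  code[coreMask] <- 1L
  code[penumbraMask] <- 2L
  png::writePNG(code / 255, target = path)
  invisible(path)
}

#' Read an integer-coded mask PNG
#' @param path PNG path written by [writeMaskPng()].
#' @return list with logical `core` and `penumbra` matrices.
#' @export
readMaskPng <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  code <- round(v * 255)
  list(core = code == 1, penumbra = code == 2)
}
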