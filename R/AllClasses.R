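#' @import methods
NULL

#' Raw CT slice in Hounsfield units
#'
#' Container for one axial CT slice as acquired: a rectangular grid of
#' Hounsfield-unit values (water = 0, air about -1000) plus the physical
#' in-plane pixel spacing, slice thickness, and the slice's ordinal position
#' in its volume. Objects are created by [ctSlice()] or [readVolume()].
#'
#' @slot hu numeric matrix of Hounsfield-unit values.
#' @slot pixelSpacing numeric length-2, mm per pixel (row, column); both > 0.
#' @slot sliceThickness numeric scalar, mm; > 0.
#' @slot sliceIndex integer ordinal position within the volume.
#' @export
setClass("CTSlice",
  representation(hu = "matrix", pixelSpacing = "numeric",
                 sliceThickness = "numeric", sliceIndex = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@hu) || any(!is.finite(object@hu)))
      msg <- c(msg, "'hu' must be a finite numeric matrix")
    if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
      msg <- c(msg, "'pixelSpacing' must be two positive values")
    if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
      msg <- c(msg, "'sliceThickness' must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Windowed CT image in the unit intensity range
#'
#' A display-windowed CT slice: intensities in [0, 1], either one plane or
#' three identical planes (the RGB tensor-shape convention used so that the
#' parameter generator and downstream segmenters see 3-channel input; no
#' chromatic information is ever introduced). Filter primitives may return
#' transient out-of-range values (e.g. an additive brightness shift before
#' the pipeline clip); the validity check therefore only requires finite
#' values, and [enhance()] guarantees the final [0, 1] range.
#'
#' @slot values numeric array H x W x C with C of 1 or 3.
#' @export
setClass("WindowedImage",
  representation(values = "array"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("'values' must be an H x W x C array")
    if (!d[3L] %in% c(1L, 3L)) return("channels must be 1 or 3")
    if (any(!is.finite(object@values))) return("values must be finite")
    TRUE
  })

#' Bank of pretrained convolution kernels with learnable mixture weights
#'
#' Holds N fixed spatial convolution kernels (typically 5x5, 7x7 and 11x11,
#' extracted from the skip convolutions of a pretrained U-Net) together with
#' unconstrained mixture logits; the effective combination weights are their
#' softmax and always sum to one. The manifest records provenance (source
#' task, reduction rule, seed).
#'
#' @slot kernels list of odd-sized numeric matrices.
#' @slot alphaLogits numeric vector, one logit per kernel.
#' @slot manifest list of provenance metadata.
#' @export
setClass("KernelBank",
  representation(kernels = "list", alphaLogits = "numeric", manifest = "list"),
  validity = function(object) {
    if (length(object@kernels) < 1L) return("bank must hold at least one kernel")
    for (k in object@kernels) {
      if (!is.matrix(k) || any(!is.finite(k))) return("kernels must be finite matrices")
      if (nrow(k) %% 2L == 0L || ncol(k) %% 2L == 0L) return("kernel sizes must be odd")
    }
    if (length(object@alphaLogits) != length(object@kernels))
      return("one logit per kernel required")
    if (any(!is.finite(object@alphaLogits))) return("logits must be finite")
    TRUE
  })

#' Synthetic brain-CT phantom with lesion masks and degraded twin
#'
#' One sample from the synthetic-data generator: a clean windowed slice, a
#' (possibly empty) soft-degraded twin, disjoint binary core and penumbra
#' masks inside the brain region, the generating seed and the record of every
#' degradation parameter drawn.
#'
#' @slot clean WindowedImage.
#' @slot degraded WindowedImage or NULL (empty image of size 0 when unset).
#' @slot coreMask logical matrix.
#' @slot penumbraMask logical matrix.
#' @slot seed integer.
#' @slot paramsApplied list.
#' @export
setClass("PhantomSample",
  representation(clean = "WindowedImage", degraded = "ANY",
                 coreMask = "matrix", penumbraMask = "matrix",
                 seed = "integer", paramsApplied = "list"),
  validity = function(object) {
    d <- dim(object@clean@values)
    if (!is.logical(object@coreMask) || !is.logical(object@penumbraMask))
      return("masks must be logical matrices")
    if (!all(dim(object@coreMask) == d[1:2]) || !all(dim(object@penumbraMask) == d[1:2]))
      return("mask shape must match the clean image")
    if (any(object@coreMask & object@penumbraMask))
      return("core and penumbra masks must be disjoint")
    TRUE
  })

## ---- constructors and accessors -----------------------------------------

#' Construct a CTSlice
#'
#' @param hu numeric matrix of Hounsfield-unit values.
#' @param pixelSpacing mm per pixel in-plane; default the anisotropic
#'   (0.5, 0.5) mm grid typical of stroke NCCT protocols.
#' @param sliceThickness slice thickness in mm (default 5).
#' @param sliceIndex ordinal slice position (default 1).
#' @return a [CTSlice-class] object.
#' @export
ctSlice <- function(hu, pixelSpacing = c(0.5, 0.5), sliceThickness = 5,
                    sliceIndex = 1L) {
  new("CTSlice", hu = as.matrix(hu), pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness),
      sliceIndex = as.integer(sliceIndex))
}

#' Construct a WindowedImage
#'
#' @param values numeric matrix (one channel) or H x W x C array, C = 1 or 3.
#' @param strict if TRUE (default) values must already lie in [0, 1].
#' @return a [WindowedImage-class] object.
#' @export
windowedImage <- function(values, strict = TRUE) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (isTRUE(strict) && (min(values) < 0 || max(values) > 1))
    stop("windowed intensities must lie in [0, 1]; use strict = FALSE for raw filter output")
  new("WindowedImage", values = values)
}

#' Intensity values of a WindowedImage
#' @param x a WindowedImage.
#' @param drop if TRUE and single-channel, return a matrix.
#' @return numeric array (or matrix when `drop` and one channel).
#' @export
imageValues <- function(x, drop = FALSE) {
  v <- x@values
  if (drop && dim(v)[3L] == 1L) return(v[, , 1L])
  v
}

#' Number of channels of a WindowedImage
#' @param x a WindowedImage.
#' @return integer, 1 or 3.
#' @export
numChannels <- function(x) dim(x@values)[3L]

#' Construct a KernelBank
#'
#' @param kernels list of odd-sized numeric matrices.
#' @param alphaLogits mixture logits, default all zero (equal weights).
#' @param manifest optional provenance list.
#' @return a [KernelBank-class] object.
#' @export
kernelBank <- function(kernels, alphaLogits = rep(0, length(kernels)),
                       manifest = list()) {
  kernels <- lapply(kernels, as.matrix)
  new("KernelBank", kernels = kernels, alphaLogits = as.numeric(alphaLogits),
      manifest = manifest)
}

#' Softmax-normalised combination weights of a KernelBank
#' @param bank a KernelBank.
#' @return numeric vector summing to one.
#' @export
bankAlphas <- function(bank) .softmax(bank@alphaLogits)

#' Kernels held by a KernelBank
#' @param bank a KernelBank.
#' @return list of matrices.
#' @export
bankKernels <- function(bank) bank@kernels

## ---- show methods --------------------------------------------------------

setMethod("show", "CTSlice", function(object) {
  d <- dim(object@hu)
  cat(sprintf("CTSlice %d x %d, HU range [%d, %d], spacing %.2f x %.2f mm, thickness %.1f mm, index %d\n",
              d[1], d[2], round(min(object@hu)), round(max(object@hu)),
              object@pixelSpacing[1], object@pixelSpacing[2],
              object@sliceThickness, object@sliceIndex))
})

setMethod("show", "WindowedImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("WindowedImage %d x %d x %d, intensity range [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(object@values), max(object@values)))
})

setMethod("show", "KernelBank", function(object) {
  sz <- vapply(object@kernels, nrow, integer(1))
  a <- bankAlphas(object)
  cat(sprintf("KernelBank of %d kernels (%s); alphas = %s\n",
              length(sz), paste0(sz, "x", sz, collapse = " + "),
              paste(sprintf("%.3f", a), collapse = ", ")))
})

setMethod("show", "PhantomSample", function(object) {
  d <- dim(object@clean@values)
  cat(sprintf("PhantomSample %d x %d (seed %d): |core| = %d px, |penumbra| = %d px, degraded twin: %s\n",
              d[1], d[2], object@seed, sum(object@coreMask), sum(object@penumbraMask),
              if (is(object@degraded, "WindowedImage")) "yes" else "no"))
})
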