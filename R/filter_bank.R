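## The bank of predefined differentiable filters. Every filter is a pure
## transform F(I, params); the pipeline consumes residuals
## Delta = F(I, params) - I so that neutral parameters leave the image
## untouched (see the methods vignette for why the residual convention is
## adopted for the summation of filter outputs).

## ---- fixed sharpness matrices -------------------------------------------

## 5x5 binomial-like base kernel with a strongly negative centre; its entries
## sum to -256. The companion map matrix M has 0.8 on the outer ring, 0.9 on
## the middle ring and 1 at the centre and sums to 21, so the normaliser
## nu(q) = sum(K + M q) = -256 + 21 q never vanishes on q in [-1, 1].
.SHARP_K <- matrix(c(
  1,  4,    6,  4, 1,
  4, 16,   24, 16, 4,
  6, 24, -476, 24, 6,
  4, 16,   24, 16, 4,
  1,  4,    6,  4, 1), 5, 5, byrow = TRUE)

.SHARP_M <- matrix(c(
  0.8, 0.8, 0.8, 0.8, 0.8,
  0.8, 0.9, 0.9, 0.9, 0.8,
  0.8, 0.9, 1.0, 0.9, 0.8,
  0.8, 0.9, 0.9, 0.9, 0.8,
  0.8, 0.8, 0.8, 0.8, 0.8), 5, 5, byrow = TRUE)

#' Fixed sharpness-filter matrices and their normaliser
#'
#' Returns the predefined 5x5 base matrix K, the map matrix M and the
#' normaliser function nu(q) = sum(K + M q) = -256 + 21 q used by
#' [applySharpness()].
#'
#' @return list with elements `K`, `M` and function `nu(q)`.
#' @export
sharpnessSpec <- function() {
  list(K = .SHARP_K, M = .SHARP_M, nu = function(q) sum(.SHARP_K) + sum(.SHARP_M) * q)
}

## ---- Gaussian -----------------------------------------------------------

#' Sampled, renormalised Gaussian convolution kernel
#'
#' Samples the centred 2-D Gaussian exp(-(x^2+y^2)/(2 sigma^2)) / (2 pi
#' sigma^2) on the integer grid x, y in -k..k and renormalises the samples to
#' sum exactly to one, giving a (2k+1) x (2k+1) low-pass kernel.
#'
#' @param sigma standard deviation in pixels, > 0.
#' @param k half-width; the kernel spans (2k+1) x (2k+1) (default 2, i.e. 5x5).
#' @return numeric matrix summing to 1.
#' @export
gaussianKernel <- function(sigma, k = 2L) {
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be at least 1")
  g1 <- exp(-(seq.int(-k, k))^2 / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern / sum(kern)
}

#' @keywords internal
.gaussian1d <- function(sigma, k) {
  g <- exp(-(seq.int(-k, k))^2 / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian blur with reflect padding
#'
#' Convolves each channel with [gaussianKernel()] (separably, since the
#' centred Gaussian factorises; the separable path agrees with dense 2-D
#' convolution to floating tolerance). Constant images are preserved because
#' the kernel sums to one.
#'
#' @param img a [WindowedImage-class].
#' @param sigma Gaussian standard deviation in pixels, > 0.
#' @param k kernel half-width (default 2).
#' @param separable use the separable two-pass path (default TRUE).
#' @return a [WindowedImage-class].
#' @export
gaussianBlur <- function(img, sigma, k = 2L, separable = TRUE) {
  stopifnot(is(img, "WindowedImage"))
  if (separable) {
    v <- .convolveSeparable(img@values, .gaussian1d(sigma, as.integer(k)))
  } else {
    v <- convolveReflect(img@values, gaussianKernel(sigma, k))
  }
  if (is.matrix(v)) v <- array(v, c(dim(v), 1L))
  new("WindowedImage", values = v)
}

## ---- sharpness ----------------------------------------------------------

#' Sharpness filter with trainable per-channel intensity
#'
#' Convolves each channel with the normalised kernel (K + M q) / nu(q),
#' where K and M are the fixed matrices of [sharpnessSpec()], q in [-1, 1]
#' is the per-channel sharpening intensity and nu(q) = -256 + 21 q. The
#' normalised kernel sums to one for every q, so constants are preserved.
#'
#' @param img a [WindowedImage-class].
#' @param q numeric, one intensity per channel in [-1, 1] (recycled across
#'   channels if scalar).
#' @return a [WindowedImage-class] (possibly out of [0, 1]; the pipeline clips).
#' @export
applySharpness <- function(img, q) {
  stopifnot(is(img, "WindowedImage"))
  nc <- numChannels(img)
  q <- rep_len(q, nc)
  if (any(abs(q) > 1)) stop("'q' must lie in [-1, 1]")
  spec <- sharpnessSpec()
  planes <- .asPlaneList(img@values)
  out <- vector("list", nc)
  for (c in seq_len(nc)) {
    nu <- spec$nu(q[c])
    if (abs(nu) < 1e-6) stop("sharpness normaliser too close to zero")
    out[[c]] <- .convolvePlane(planes[[c]], (spec$K + spec$M * q[c]) / nu)
  }
  v <- .fromPlaneList(out)
  if (is.matrix(v)) v <- array(v, c(dim(v), 1L))
  new("WindowedImage", values = v)
}

## ---- contrast -----------------------------------------------------------

#' @keywords internal
.contrastScale <- function(r) if (r > 0) 1 / (1 - r) else 1 - r

#' Contrast filter
#'
#' Rescales intensities about mid-gray by s(r) = 1/(1-r) for r > 0 and
#' (1 - r) otherwise. The default mode restores the 0.5 offset,
#' 0.5 + (I - 0.5) s(r), so r = 0 is the identity; `literal = TRUE` keeps
#' the bare form (I - 0.5) s(r), which shifts the image by -0.5 and is kept
#' for fidelity to the filter's published formulation.
#'
#' @param img a [WindowedImage-class].
#' @param r contrast parameter in [-1, 1); r = 1 would imply infinite gain.
#' @param literal use the bare (I - 0.5) s(r) form (default FALSE).
#' @return a [WindowedImage-class] (unclipped).
#' @export
applyContrast <- function(img, r, literal = FALSE) {
  stopifnot(is(img, "WindowedImage"))
  if (!is.finite(r) || r < -1 || r >= 1) stop("'r' must lie in [-1, 1)")
  s <- .contrastScale(r)
  v <- (img@values - 0.5) * s
  if (!literal) v <- v + 0.5
  new("WindowedImage", values = v)
}

#' Global brightness filter
#'
#' Additive brightness shift I + b, b in [-1, 1]. Clipping is deferred to
#' the enhancement pipeline so that the residual is exactly the constant b.
#'
#' @param img a [WindowedImage-class].
#' @param b brightness offset in [-1, 1].
#' @return a [WindowedImage-class] (unclipped).
#' @export
applyBrightness <- function(img, b) {
  stopifnot(is(img, "WindowedImage"))
  if (!is.finite(b) || abs(b) > 1) stop("'b' must lie in [-1, 1]")
  new("WindowedImage", values = img@values + b)
}

#' Median filter (exact, non-trainable)
#'
#' Replaces each pixel with the exact median of its window (reflect
#' padding). The 3x3 case runs through a vectorised min/max selection
#' network. The filter is excluded from gradient-based training.
#'
#' @param img a [WindowedImage-class].
#' @param window odd window side length, at least 3 (default 3).
#' @return a [WindowedImage-class].
#' @export
applyMedian <- function(img, window = 3L) {
  stopifnot(is(img, "WindowedImage"))
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) stop("'window' must be odd and >= 3")
  planes <- lapply(.asPlaneList(img@values), .medianPlane, window = window)
  v <- .fromPlaneList(planes)
  if (is.matrix(v)) v <- array(v, c(dim(v), 1L))
  new("WindowedImage", values = v)
}

## ---- pretrained-kernel combination --------------------------------------

#' Softmax-weighted combination of pretrained convolution kernels
#'
#' Applies each kernel of the bank to every channel (reflect padding) and
#' combines the results with the bank's softmax weights:
#' sum_i alpha_i (K_i * I). The weights always sum to one.
#'
#' @param img a [WindowedImage-class].
#' @param bank a [KernelBank-class].
#' @return a [WindowedImage-class] (unclipped).
#' @export
applyKernelCombo <- function(img, bank) {
  stopifnot(is(img, "WindowedImage"))
  if (!is(bank, "KernelBank")) stop("'bank' must be a KernelBank")
  a <- bankAlphas(bank)
  v <- 0
  for (i in seq_along(a))
    v <- v + a[i] * convolveReflect(img@values, bank@kernels[[i]])
  if (is.matrix(v)) v <- array(v, c(dim(v), 1L))
  new("WindowedImage", values = v)
}

## ---- registry and residuals ---------------------------------------------

## Registry addressed by the ablation-table row vocabulary. Each entry maps
## (img, params, bank) to the full transform output.
.filterRegistry <- new.env(parent = emptyenv())

#' @keywords internal
.registerFilters <- function() {
  reg <- .filterRegistry
  reg[["brightness"]]    <- function(img, params, bank) applyBrightness(img, params$b)
  reg[["contrast"]]      <- function(img, params, bank) applyContrast(img, params$r,
                                      literal = isTRUE(params$literal))
  reg[["sharpen"]]       <- function(img, params, bank) applySharpness(img, params$q)
  reg[["gaussian blur"]] <- function(img, params, bank) gaussianBlur(img, params$sigma,
                                      k = if (is.null(params$k)) 2L else params$k)
  reg[["median filter"]] <- function(img, params, bank) applyMedian(img,
                                      if (is.null(params$window)) 3L else params$window)
  reg[["CB 5x5+7x7+11x11"]] <- function(img, params, bank) applyKernelCombo(img, bank)
  invisible(NULL)
}

#' Names of the registered filters
#' @return character vector of registry keys.
#' @export
filterNames <- function() ls(.filterRegistry)

#' Apply a registered filter by name
#'
#' @param name registry key, one of [filterNames()].
#' @param img a [WindowedImage-class].
#' @param params named list of the filter's parameters.
#' @param bank optional [KernelBank-class] (required for the "CB" filter).
#' @return the transformed [WindowedImage-class].
#' @export
applyFilter <- function(name, img, params = list(), bank = NULL) {
  if (length(ls(.filterRegistry)) == 0L) .registerFilters()
  f <- .filterRegistry[[name]]
  if (is.null(f)) stop("unknown filter '", name, "'; see filterNames()")
  if (name == "CB 5x5+7x7+11x11" && is.null(bank))
    stop("the pretrained-kernel filter requires a KernelBank")
  f(img, params, bank)
}

#' Residual of a registered filter
#'
#' Delta = F(img, params) - img, the form in which the enhancement pipeline
#' sums filter contributions so that neutral parameters contribute nothing.
#'
#' @inheritParams applyFilter
#' @return numeric array of the same shape as the image values.
#' @export
filterResidual <- function(name, img, params = list(), bank = NULL) {
  out <- applyFilter(name, img, params, bank)
  out@values - img@values
}
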