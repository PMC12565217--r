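## Composition of generator and filter bank: downscale the slice, predict
## the scalar filter parameters, add every filter's residual to the original
## full-resolution image, clip to [0, 1]. With all gains zero (or neutral
## parameters for the filters that admit an identity point) the pipeline is
## the bit-exact identity, which is the formal artifact-safety anchor.

#' Pipeline configuration
#'
#' @param filters ordered character vector of registry names (see
#'   [filterNames()]); default is the winning combination: pretrained-kernel
#'   block + brightness + sharpen + contrast.
#' @param gains fixed per-filter gains w_i applied to each residual
#'   (default 1; gains exist for neutrality tests and ablations, they are
#'   not learned).
#' @param generator a generator configuration from [generatorConfig()].
#' @param bank a [KernelBank-class]; required when the "CB" filter is active.
#' @return list, the validated configuration.
#' @export
pipelineConfig <- function(filters = c("CB 5x5+7x7+11x11", "brightness",
                                       "sharpen", "contrast"),
                           gains = rep(1, length(filters)),
                           generator = generatorConfig(
                             headSpec = defaultHeadSpec(blur = "gaussian blur" %in% filters)),
                           bank = NULL) {
  if (length(ls(.filterRegistry)) == 0L) .registerFilters()
  unknown <- setdiff(filters, filterNames())
  if (length(unknown)) stop("unknown filter(s): ", paste(unknown, collapse = ", "))
  if (length(gains) != length(filters)) stop("one gain per filter required")
  if ("CB 5x5+7x7+11x11" %in% filters && is.null(bank))
    stop("the pretrained-kernel filter requires 'bank'")
  list(filters = filters, gains = as.numeric(gains), generator = generator,
       bank = bank)
}

#' Neutral parameter set of a pipeline
#'
#' The parameter values whose residuals vanish for every filter that admits
#' an identity point (brightness 0, contrast 0, blur sigma -> 0). Filters
#' with no identity point at any parameter value (the sharpness kernel is
#' never a discrete delta, nor is the pretrained-kernel combination) are
#' flagged: their neutrality is only reachable through a zero gain.
#'
#' @param cfg a pipeline configuration.
#' @return named list of parameter groups with attribute `flagged`, the
#'   names of filters lacking an identity point.
#' @export
neutralParams <- function(cfg) {
  out <- list()
  flagged <- character()
  for (f in cfg$filters) {
    switch(f,
      "brightness" = { out$brightness <- list(b = 0) },
      "contrast" = { out$contrast <- list(r = 0) },
      "gaussian blur" = { out$blur <- list(sigma = 0) },
      "sharpen" = { out$sharpen <- list(q = c(0, 0, 0))
                    flagged <- c(flagged, "sharpen") },
      "CB 5x5+7x7+11x11" = { out$cb <- list(logits = c(0, 0, 0))
                             flagged <- c(flagged, "CB 5x5+7x7+11x11") },
      "median filter" = { flagged <- c(flagged, "median filter") })
  }
  attr(out, "flagged") <- flagged
  out
}

#' Enhance an image with explicit filter parameters
#'
#' Applies Ie = clip(Io + sum_i w_i * Delta_i(Io, p_i), 0, 1) with the given
#' parameter groups (as returned by [predictParams()] or [neutralParams()]).
#'
#' @param img a 3-channel [WindowedImage-class] in [0, 1].
#' @param params named list of parameter groups.
#' @param cfg a pipeline configuration.
#' @return the enhanced [WindowedImage-class], clipped to [0, 1].
#' @export
enhanceWithParams <- function(img, params, cfg) {
  stopifnot(is(img, "WindowedImage"))
  io <- img@values
  acc <- io
  bank <- cfg$bank
  for (i in seq_along(cfg$filters)) {
    w <- cfg$gains[i]
    if (w == 0) next
    f <- cfg$filters[i]
    p <- switch(f,
      "brightness" = params$brightness,
      "contrast" = params$contrast,
      "sharpen" = list(q = rep_len(params$sharpen$q, dim(io)[3])),
      "gaussian blur" = params$blur,
      "median filter" = list(),
      "CB 5x5+7x7+11x11" = params$cb)
    if (f == "gaussian blur" && (is.null(p$sigma) || p$sigma < 1e-6)) next
    if (f == "CB 5x5+7x7+11x11") {
      b <- bank
      if (!is.null(p$logits)) b@alphaLogits <- as.numeric(p$logits)
      delta <- filterResidual(f, img, list(), b)
    } else {
      pl <- if (f == "brightness") list(b = p$b)
            else if (f == "contrast") list(r = p$r)
            else if (f == "sharpen") list(q = p$q)
            else if (f == "gaussian blur") list(sigma = p$sigma)
            else list()
      delta <- filterResidual(f, img, pl, bank)
    }
    acc <- acc + w * delta
  }
  new("WindowedImage", values = .clip01(acc))
}

#' Enhance an image with generator-predicted parameters
#'
#' Downscales the input to the generator resolution, predicts the filter
#' parameters and applies [enhanceWithParams()] at full resolution. The full
#' input resolution is preserved; the premise is that the predicted
#' point/convolution transforms are consistent across scales.
#'
#' @param img a 3-channel [WindowedImage-class], side length at least the
#'   generator input size.
#' @param gen a [ParamGenerator-class].
#' @param cfg a pipeline configuration from [pipelineConfig()].
#' @return the enhanced [WindowedImage-class].
#' @export
enhance <- function(img, gen, cfg) {
  stopifnot(is(img, "WindowedImage"))
  if (numChannels(img) == 1L) img <- triplicateChannels(img)
  small <- downscaleImage(img, gen@config$inputSize)
  params <- predictParams(gen, small)
  enhanceWithParams(img, params, cfg)
}

## ---- fast path for training ---------------------------------------------
## All residuals of the default filter set are cheap functions of a handful
## of convolutions of the *input* image, which therefore only need computing
## once per image per optimisation step. basis$ components:
##   io            H x W x C input
##   convK, convM  sharpness base convolutions (per channel)
##   cb            list of per-kernel convolutions
## The residual and the analytic parameter-derivative images are then
## elementwise combinations.

#' @keywords internal
.residualBasis <- function(io, cfg) {
  basis <- list(io = io, filters = cfg$filters, gains = cfg$gains)
  if ("sharpen" %in% cfg$filters) {
    spec <- sharpnessSpec()
    basis$convK <- convolveReflect(io, spec$K)
    basis$convM <- convolveReflect(io, spec$M)
  }
  if ("CB 5x5+7x7+11x11" %in% cfg$filters) {
    basis$cb <- lapply(cfg$bank@kernels, function(k) convolveReflect(io, k))
  }
  basis
}

## params is the named group list; returns the *pre-clip* sum image.
#' @keywords internal
.enhanceFromBasis <- function(basis, params) {
  io <- basis$io
  acc <- io
  for (i in seq_along(basis$filters)) {
    w <- basis$gains[i]
    if (w == 0) next
    switch(basis$filters[i],
      "brightness" = { acc <- acc + w * params$brightness$b },
      "contrast" = {
        s <- .contrastScale(params$contrast$r)
        acc <- acc + w * (io - 0.5) * (s - 1)
      },
      "sharpen" = {
        q <- rep_len(params$sharpen$q, dim(io)[3])
        spec <- sharpnessSpec()
        for (c in seq_len(dim(io)[3])) {
          nu <- spec$nu(q[c])
          acc[, , c] <- acc[, , c] +
            w * ((basis$convK[, , c] + q[c] * basis$convM[, , c]) / nu - io[, , c])
        }
      },
      "CB 5x5+7x7+11x11" = {
        a <- .softmax(params$cb$logits)
        mix <- 0
        for (j in seq_along(a)) mix <- mix + a[j] * basis$cb[[j]]
        acc <- acc + w * (mix - io)
      },
      "gaussian blur" = {
        if (!is.null(params$blur$sigma) && params$blur$sigma >= 1e-6) {
          blur <- .convolveSeparable(io, .gaussian1d(params$blur$sigma, 2L))
          acc <- acc + w * (blur - io)
        }
      })
  }
  acc
}

## Analytic d(preclip)/d(parameter) images in head order, as a list matching
## the head-spec parameter layout (cb logits, b, q1..3, r, [sigma]).
#' @keywords internal
.residualParamDerivs <- function(basis, params) {
  io <- basis$io
  nc <- dim(io)[3]
  derivs <- list()
  for (i in seq_along(basis$filters)) {
    w <- basis$gains[i]
    switch(basis$filters[i],
      "CB 5x5+7x7+11x11" = {
        a <- .softmax(params$cb$logits)
        mix <- 0
        for (j in seq_along(a)) mix <- mix + a[j] * basis$cb[[j]]
        derivs$cb <- lapply(seq_along(a), function(j)
          w * a[j] * (basis$cb[[j]] - mix))
      },
      "brightness" = { derivs$brightness <- w },
      "sharpen" = {
        q <- rep_len(params$sharpen$q, nc)
        spec <- sharpnessSpec()
        sM <- sum(spec$M)
        derivs$sharpen <- lapply(seq_len(nc), function(c) {
          nu <- spec$nu(q[c])
          num <- basis$convK[, , c] + q[c] * basis$convM[, , c]
          w * (basis$convM[, , c] * nu - num * sM) / nu^2
        })
      },
      "contrast" = {
        r <- params$contrast$r
        ds <- if (r > 0) 1 / (1 - r)^2 else -1
        derivs$contrast <- w * (io - 0.5) * ds
      })
  }
  derivs
}
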