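## The compact parameter-generator network h: a downscaled 3 x 128 x 128 copy
## of the slice goes through three stride-2 conv/BN/ReLU blocks (widths
## 32/64/128, giving a 128-channel 16 x 16 feature map), then two fully
## connected layers, then per-filter range activations (sigmoid for [0,1],
## tanh for [-1,1], identity for unconstrained logits). The "lite" variant
## replaces the 32,768-feature flatten with global average pooling, keeping
## the network genuinely lightweight; the "paper-faithful" variant keeps the
## flatten.

#' Parameter generator network
#'
#' S4 wrapper around the generator's configuration, weights and batch-norm
#' running statistics. Created by [buildGenerator()]; used by
#' [predictParams()] and [enhance()].
#'
#' @slot config list: convWidths, fcHidden, variant, inputSize, headSpec.
#' @slot weights named list of weight arrays.
#' @slot bnStats list of running mean/var per batch-norm layer.
#' @export
setClass("ParamGenerator",
  representation(config = "list", weights = "list", bnStats = "list"))

#' Default head specification for the winning filter combination
#'
#' One row per parameter group: the pretrained-kernel combination logits
#' (free range, softmax applied inside the filter), global brightness
#' (signed), per-channel sharpness intensity (signed) and contrast (signed).
#' An optional blur head (unit range, scaled to (0, sigmaMax]) can be added
#' with `blur = TRUE`.
#'
#' @param blur include a Gaussian-blur sigma head (default FALSE).
#' @return data.frame with columns `filter`, `count`, `range`.
#' @export
defaultHeadSpec <- function(blur = FALSE) {
  hs <- data.frame(
    filter = c("cb", "brightness", "sharpen", "contrast"),
    count = c(3L, 1L, 3L, 1L),
    range = c("free", "signed", "signed", "signed"),
    stringsAsFactors = FALSE)
  if (blur) hs <- rbind(hs, data.frame(filter = "blur", count = 1L, range = "unit"))
  hs
}

#' Generator configuration
#'
#' @param convWidths channel widths of the three stride-2 blocks
#'   (default 32, 64, 128).
#' @param fcHidden hidden units of the first fully connected layer (512).
#' @param variant "lite" (global average pooling, default) or
#'   "paper-faithful" (flatten the 16 x 16 x 128 feature map).
#' @param inputSize generator input side length (128).
#' @param headSpec data.frame as from [defaultHeadSpec()].
#' @param sigmaMax upper bound of the blur head's sigma mapping, pixels.
#' @return list, the validated configuration.
#' @export
generatorConfig <- function(convWidths = c(32L, 64L, 128L), fcHidden = 512L,
                            variant = c("lite", "paper-faithful"),
                            inputSize = 128L, headSpec = defaultHeadSpec(),
                            sigmaMax = 2.0) {
  variant <- match.arg(variant)
  stopifnot(length(convWidths) == 3L, all(convWidths >= 1))
  if (nrow(headSpec) == 0L) stop("'headSpec' must contain at least one head")
  if (!all(headSpec$range %in% c("unit", "signed", "free")))
    stop("head ranges must be 'unit', 'signed' or 'free'")
  list(convWidths = as.integer(convWidths), fcHidden = as.integer(fcHidden),
       variant = variant, inputSize = as.integer(inputSize),
       headSpec = headSpec, sigmaMax = sigmaMax)
}

#' Build a parameter generator with seeded initialisation
#'
#' @param cfg configuration from [generatorConfig()].
#' @param seed integer RNG seed; the same seed gives bit-identical weights.
#' @return a [ParamGenerator-class].
#' @export
buildGenerator <- function(cfg = generatorConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  cw <- cfg$convWidths
  inCh <- 3L
  w <- list()
  chain <- c(inCh, cw)
  for (i in 1:3) {
    fanIn <- 9L * chain[i]
    w[[paste0("conv", i, "_W")]] <- .heInit(c(3L, 3L, chain[i], chain[i + 1]), fanIn)
    w[[paste0("conv", i, "_b")]] <- numeric(chain[i + 1])
    w[[paste0("bn", i, "_gamma")]] <- rep(1, chain[i + 1])
    w[[paste0("bn", i, "_beta")]] <- numeric(chain[i + 1])
  }
  featSize <- cfg$inputSize %/% 8L
  fcIn <- if (cfg$variant == "lite") cw[3] else cw[3] * featSize * featSize
  nOut <- sum(cfg$headSpec$count)
  w$fc1_W <- .heInit(c(fcIn, cfg$fcHidden), fcIn)
  w$fc1_b <- numeric(cfg$fcHidden)
  # zero-initialised head: all raw outputs start at 0, i.e. neutral
  # brightness/contrast/sharpness and equal kernel-combination weights, so
  # the untrained pipeline starts as close to the identity as the filter
  # set allows
  w$fc2_W <- array(0, c(cfg$fcHidden, nOut))
  w$fc2_b <- numeric(nOut)
  bn <- lapply(1:3, function(i) list(mean = numeric(cw[i]), var = rep(1, cw[i])))
  names(bn) <- paste0("bn", 1:3)
  new("ParamGenerator", config = cfg, weights = w, bnStats = bn)
}

#' Total trainable parameter count of a generator
#' @param gen a [ParamGenerator-class].
#' @return integer count.
#' @export
generatorParamCount <- function(gen) {
  sum(vapply(gen@weights, length, integer(1)))
}

setMethod("show", "ParamGenerator", function(object) {
  cat(sprintf("ParamGenerator (%s): conv widths %s, fc %d, %d head outputs, %d trainable parameters\n",
              object@config$variant,
              paste(object@config$convWidths, collapse = "/"),
              object@config$fcHidden, sum(object@config$headSpec$count),
              generatorParamCount(object)))
})

## Forward pass. x is H x W x 3 in [0,1]; returns the raw head vector, the
## activated vector and (if train or needCache) the cache for backprop.
#' @keywords internal
.genForward <- function(gen, x, train = FALSE, needCache = train) {
  w <- gen@weights
  cfg <- gen@config
  cache <- list(x = x)
  a <- x
  bnStats <- gen@bnStats
  for (i in 1:3) {
    z <- .convF(a, w[[paste0("conv", i, "_W")]], w[[paste0("conv", i, "_b")]],
                stride = 2L, pad = 1L)
    bn <- .bnF(z, w[[paste0("bn", i, "_gamma")]], w[[paste0("bn", i, "_beta")]],
               bnStats[[paste0("bn", i)]], train = train)
    bnStats[[paste0("bn", i)]] <- bn$running
    r <- .reluF(bn$y)
    if (needCache) {
      cache[[paste0("in", i)]] <- a
      cache[[paste0("bnc", i)]] <- bn$cache
      cache[[paste0("pre", i)]] <- bn$y
    }
    a <- r
  }
  d <- dim(a)
  if (cfg$variant == "lite") {
    feat <- colMeans(matrix(a, d[1] * d[2], d[3]))
  } else {
    feat <- as.numeric(a)
  }
  h1 <- as.numeric(feat %*% w$fc1_W) + w$fc1_b
  r1 <- .reluF(h1)
  z2 <- as.numeric(r1 %*% w$fc2_W) + w$fc2_b
  if (needCache) {
    cache$featDim <- d; cache$feat <- feat; cache$h1 <- h1; cache$r1 <- r1
  }
  act <- .activateHeads(z2, cfg$headSpec)
  list(raw = z2, activated = act, cache = if (needCache) cache else NULL,
       bnStats = bnStats)
}

#' @keywords internal
.activateHeads <- function(z, headSpec) {
  out <- numeric(length(z))
  pos <- 0L
  for (i in seq_len(nrow(headSpec))) {
    idx <- pos + seq_len(headSpec$count[i])
    out[idx] <- switch(headSpec$range[i],
                       unit = 1 / (1 + exp(-z[idx])),
                       signed = tanh(z[idx]),
                       free = z[idx])
    pos <- pos + headSpec$count[i]
  }
  out
}

## d(activated)/d(raw) for each head output.
#' @keywords internal
.headActDeriv <- function(z, headSpec) {
  d <- numeric(length(z))
  pos <- 0L
  for (i in seq_len(nrow(headSpec))) {
    idx <- pos + seq_len(headSpec$count[i])
    d[idx] <- switch(headSpec$range[i],
                     unit = { s <- 1 / (1 + exp(-z[idx])); s * (1 - s) },
                     signed = 1 - tanh(z[idx])^2,
                     free = 1)
    pos <- pos + headSpec$count[i]
  }
  d
}

## Backward pass: dRaw is the gradient w.r.t. the raw head vector.
#' @keywords internal
.genBackward <- function(gen, cache, dRaw) {
  w <- gen@weights
  cfg <- gen@config
  g <- list()
  dR1 <- as.numeric(w$fc2_W %*% dRaw)
  g$fc2_W <- outer(cache$r1, dRaw)
  g$fc2_b <- dRaw
  dH1 <- dR1 * (cache$h1 > 0)
  g$fc1_W <- outer(cache$feat, dH1)
  g$fc1_b <- dH1
  dFeat <- as.numeric(w$fc1_W %*% dH1)
  d <- cache$featDim
  if (cfg$variant == "lite") {
    n <- d[1] * d[2]
    dA <- array(rep(dFeat / n, each = n), d)
  } else {
    dA <- array(dFeat, d)
  }
  for (i in 3:1) {
    dPre <- .reluB(cache[[paste0("pre", i)]], dA)
    bnb <- .bnB(cache[[paste0("bnc", i)]], dPre)
    g[[paste0("bn", i, "_gamma")]] <- bnb$dgamma
    g[[paste0("bn", i, "_beta")]] <- bnb$dbeta
    cb <- .convB(cache[[paste0("in", i)]], w[[paste0("conv", i, "_W")]],
                 stride = 2L, pad = 1L, dY = bnb$dx)
    g[[paste0("conv", i, "_W")]] <- cb$dW
    g[[paste0("conv", i, "_b")]] <- cb$db
    dA <- cb$dx
  }
  g
}

#' Predict filter parameters from a downscaled image
#'
#' Runs the generator in inference mode on the 3-channel generator-resolution
#' image and splits the activated head vector into named per-filter groups:
#' unit-range outputs pass through a sigmoid, signed-range through tanh,
#' free-range (the kernel-combination logits) are returned as-is.
#'
#' @param gen a [ParamGenerator-class].
#' @param img128 a 3-channel [WindowedImage-class] of the generator's input
#'   size (128 x 128 by default).
#' @return named list of parameter groups, e.g. `$brightness$b`,
#'   `$sharpen$q`, `$contrast$r`, `$cb$logits`, optionally `$blur$sigma`.
#' @export
predictParams <- function(gen, img128) {
  stopifnot(is(gen, "ParamGenerator"), is(img128, "WindowedImage"))
  d <- dim(img128@values)
  sz <- gen@config$inputSize
  if (d[1] != sz || d[2] != sz || d[3] != 3L)
    stop(sprintf("generator expects a 3 x %d x %d input, got %d x %d x %d",
                 sz, sz, d[3], d[1], d[2]))
  fw <- .genForward(gen, img128@values, train = FALSE, needCache = FALSE)
  .splitParams(fw$activated, gen@config)
}

#' @keywords internal
.splitParams <- function(act, cfg) {
  hs <- cfg$headSpec
  out <- list()
  pos <- 0L
  for (i in seq_len(nrow(hs))) {
    idx <- pos + seq_len(hs$count[i])
    vals <- act[idx]
    out[[hs$filter[i]]] <- switch(hs$filter[i],
      cb = list(logits = vals),
      brightness = list(b = vals),
      sharpen = list(q = vals),
      contrast = list(r = vals),
      blur = list(sigma = vals * cfg$sigmaMax),
      list(values = vals))
    pos <- pos + hs$count[i]
  }
  out
}

## ---- checkpoint serialisation (portable JSON) ---------------------------

#' Save a generator checkpoint as JSON
#'
#' Weights, batch-norm running statistics and the configuration are written
#' to a single JSON file at full double precision.
#'
#' @param gen a [ParamGenerator-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
saveGenerator <- function(gen, path) {
  obj <- list(
    config = gen@config[setdiff(names(gen@config), "headSpec")],
    headSpec = gen@config$headSpec,
    weights = lapply(gen@weights, function(p) list(dim = dim(p) %||% length(p),
                                                   data = as.numeric(p))),
    bnStats = gen@bnStats)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a generator checkpoint saved by [saveGenerator()]
#' @param path JSON checkpoint path.
#' @return a [ParamGenerator-class].
#' @export
loadGenerator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hs <- as.data.frame(obj$headSpec, stringsAsFactors = FALSE)
  cfg <- generatorConfig(convWidths = obj$config$convWidths,
                         fcHidden = obj$config$fcHidden,
                         variant = obj$config$variant,
                         inputSize = obj$config$inputSize,
                         headSpec = hs, sigmaMax = obj$config$sigmaMax)
  w <- lapply(obj$weights, function(p) {
    if (length(p$dim) > 1L) array(p$data, p$dim) else as.numeric(p$data)
  })
  bn <- lapply(obj$bnStats, function(s) list(mean = as.numeric(s$mean),
                                             var = as.numeric(s$var)))
  new("ParamGenerator", config = cfg, weights = w, bnStats = bn)
}
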