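## Symmetric encoder-decoder U-Net with optional skip-path convolutions of
## fixed odd sizes (5/7/11 by default). One conv+ReLU per level keeps the
## model small; the skip convolutions are linear so their weights are
## directly reusable as spatial filter kernels. Used in two roles: the
## skip-convolution network whose kernels seed the pretrained-kernel filter
## block, and (without skip convolutions) the toy segmenter of the joint
## training harness.

#' U-Net model
#'
#' @slot config list: depth, baseWidth, inCh, outCh, skipKernelSizes, task.
#' @slot weights named list of weight arrays.
#' @export
setClass("UNetModel", representation(config = "list", weights = "list"))

#' Skip-convolution U-Net configuration
#'
#' @param depth number of encoder levels, at least 3 (default 5).
#' @param baseWidth channels at the first level (default 4); level l has
#'   baseWidth * 2^(l-1) channels.
#' @param inCh,outCh input/output channel counts.
#' @param skipKernelSizes odd kernel sizes of the skip-path convolutions,
#'   assigned shallowest-to-deepest (default 5, 7, 11); NULL for plain
#'   identity skips.
#' @param task "segmentation" (Dice loss on core/penumbra) or
#'   "reconstruction" (L1).
#' @return list, the validated configuration.
#' @export
skipUNetConfig <- function(depth = 5L, baseWidth = 4L, inCh = 1L, outCh = 3L,
                           skipKernelSizes = c(5L, 7L, 11L),
                           task = c("segmentation", "reconstruction")) {
  task <- match.arg(task)
  depth <- as.integer(depth)
  if (depth < 3L) stop("'depth' must be at least 3")
  if (!is.null(skipKernelSizes)) {
    skipKernelSizes <- as.integer(skipKernelSizes)
    if (any(skipKernelSizes %% 2L == 0L)) stop("skip kernel sizes must be odd")
    if (length(skipKernelSizes) > depth - 1L)
      stop("more skip kernels than skip paths")
  }
  if (task == "reconstruction") outCh <- inCh
  list(depth = depth, baseWidth = as.integer(baseWidth), inCh = as.integer(inCh),
       outCh = as.integer(outCh), skipKernelSizes = skipKernelSizes, task = task)
}

#' Build a (skip-convolution) U-Net with seeded initialisation
#'
#' Encoder levels are conv3x3 + ReLU followed by 2x2 max pooling; the
#' decoder mirrors them with nearest-neighbour upsampling and skip
#' concatenation. Each configured skip path passes through one linear
#' convolution of the configured size with weights shared across spatial
#' positions (these are the kernels later extracted into the
#' [KernelBank-class]).
#'
#' @param cfg configuration from [skipUNetConfig()].
#' @param seed integer seed; identical seeds give identical weights.
#' @return a [UNetModel-class].
#' @export
buildSkipUNet <- function(cfg = skipUNetConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  L <- cfg$depth
  ch <- cfg$baseWidth * 2L^(seq_len(L) - 1L)
  w <- list()
  prev <- cfg$inCh
  for (l in seq_len(L)) {
    w[[paste0("enc", l, "_W")]] <- .heInit(c(3L, 3L, prev, ch[l]), 9L * prev)
    w[[paste0("enc", l, "_b")]] <- numeric(ch[l])
    prev <- ch[l]
  }
  if (!is.null(cfg$skipKernelSizes)) {
    for (i in seq_along(cfg$skipKernelSizes)) {
      k <- cfg$skipKernelSizes[i]
      w[[paste0("skip", i, "_W")]] <- .heInit(c(k, k, ch[i], ch[i]), k * k * ch[i])
      w[[paste0("skip", i, "_b")]] <- numeric(ch[i])
    }
  }
  for (l in seq_len(L - 1L)) {
    fanIn <- 9L * (ch[l + 1L] + ch[l])
    w[[paste0("dec", l, "_W")]] <- .heInit(c(3L, 3L, ch[l + 1L] + ch[l], ch[l]), fanIn)
    w[[paste0("dec", l, "_b")]] <- numeric(ch[l])
  }
  w$head_W <- .heInit(c(1L, 1L, ch[1], cfg$outCh), ch[1])
  w$head_b <- numeric(cfg$outCh)
  new("UNetModel", config = cfg, weights = w)
}

#' Build the toy segmenter used by the joint-training harness
#'
#' A plain 3-level U-Net (no skip convolutions) with three output channels
#' (background, core, penumbra).
#'
#' @param seed integer seed.
#' @param baseWidth channels at level 1 (default 8).
#' @param inCh input channels (default 3, the triplicated CT convention).
#' @return a [UNetModel-class].
#' @export
buildToySegmenter <- function(seed = 1L, baseWidth = 8L, inCh = 3L) {
  buildSkipUNet(skipUNetConfig(depth = 3L, baseWidth = baseWidth, inCh = inCh,
                               outCh = 3L, skipKernelSizes = NULL,
                               task = "segmentation"), seed = seed)
}

setMethod("show", "UNetModel", function(object) {
  np <- sum(vapply(object@weights, length, integer(1)))
  sk <- object@config$skipKernelSizes
  cat(sprintf("UNetModel depth %d, base width %d, task %s, skip convs %s, %d parameters\n",
              object@config$depth, object@config$baseWidth, object@config$task,
              if (is.null(sk)) "none" else paste(sk, collapse = "/"), np))
})

#' @keywords internal
.unetForward <- function(model, x, needCache = FALSE) {
  cfg <- model@config
  w <- model@weights
  L <- cfg$depth
  nSkip <- length(cfg$skipKernelSizes)
  cache <- list()
  a <- x
  skips <- vector("list", L - 1L)
  for (l in seq_len(L)) {
    z <- .convF(a, w[[paste0("enc", l, "_W")]], w[[paste0("enc", l, "_b")]],
                stride = 1L, pad = 1L)
    r <- .reluF(z)
    if (needCache) { cache[[paste0("encIn", l)]] <- a; cache[[paste0("encZ", l)]] <- z }
    if (l < L) {
      skips[[l]] <- r
      pl <- .pool2F(r)
      if (needCache) cache[[paste0("pool", l)]] <- pl$cache
      a <- pl$y
    } else a <- r
  }
  for (l in seq.int(L - 1L, 1L)) {
    up <- .up2F(a)
    s <- skips[[l]]
    if (l <= nSkip) {
      k <- cfg$skipKernelSizes[l]
      sIn <- s
      s <- .convF(s, w[[paste0("skip", l, "_W")]], w[[paste0("skip", l, "_b")]],
                  stride = 1L, pad = (k - 1L) %/% 2L)
      if (needCache) cache[[paste0("skipIn", l)]] <- sIn
    }
    cat_ <- array(c(up, s), c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(s)[3]))
    z <- .convF(cat_, w[[paste0("dec", l, "_W")]], w[[paste0("dec", l, "_b")]],
                stride = 1L, pad = 1L)
    r <- .reluF(z)
    if (needCache) {
      cache[[paste0("decIn", l)]] <- cat_
      cache[[paste0("decZ", l)]] <- z
      cache[[paste0("upCh", l)]] <- dim(up)[3]
    }
    a <- r
  }
  out <- .convF(a, w$head_W, w$head_b, stride = 1L, pad = 0L)
  if (needCache) cache$headIn <- a
  list(out = out, cache = if (needCache) cache else NULL)
}

## Backward pass; dOut is the gradient at the network output. Returns the
## weight gradients and the gradient w.r.t. the input (for joint training).
#' @keywords internal
.unetBackward <- function(model, cache, dOut) {
  cfg <- model@config
  w <- model@weights
  L <- cfg$depth
  nSkip <- length(cfg$skipKernelSizes)
  g <- list()
  hb <- .convB(cache$headIn, w$head_W, stride = 1L, pad = 0L, dY = dOut)
  g$head_W <- hb$dW; g$head_b <- hb$db
  dA <- hb$dx
  dSkips <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    dZ <- .reluB(cache[[paste0("decZ", l)]], dA)
    db <- .convB(cache[[paste0("decIn", l)]], w[[paste0("dec", l, "_W")]],
                 stride = 1L, pad = 1L, dY = dZ)
    g[[paste0("dec", l, "_W")]] <- db$dW
    g[[paste0("dec", l, "_b")]] <- db$db
    upCh <- cache[[paste0("upCh", l)]]
    dUp <- db$dx[, , seq_len(upCh), drop = FALSE]
    dS <- db$dx[, , upCh + seq_len(dim(db$dx)[3] - upCh), drop = FALSE]
    if (l <= nSkip) {
      k <- cfg$skipKernelSizes[l]
      sb <- .convB(cache[[paste0("skipIn", l)]], w[[paste0("skip", l, "_W")]],
                   stride = 1L, pad = (k - 1L) %/% 2L, dY = dS)
      g[[paste0("skip", l, "_W")]] <- sb$dW
      g[[paste0("skip", l, "_b")]] <- sb$db
      dS <- sb$dx
    }
    dSkips[[l]] <- dS
    dA <- .up2B(dUp)
  }
  # encoder, deepest level first
  for (l in seq.int(L, 1L)) {
    if (l < L) {
      dPool <- .pool2B(cache[[paste0("pool", l)]], dA)
      dR <- dPool + dSkips[[l]]
    } else dR <- dA
    dZ <- .reluB(cache[[paste0("encZ", l)]], dR)
    eb <- .convB(cache[[paste0("encIn", l)]], w[[paste0("enc", l, "_W")]],
                 stride = 1L, pad = 1L, dY = dZ)
    g[[paste0("enc", l, "_W")]] <- eb$dW
    g[[paste0("enc", l, "_b")]] <- eb$db
    dA <- eb$dx
  }
  list(grads = g, dx = dA)
}

#' Per-pixel softmax over the channel dimension
#' @keywords internal
.softmaxChannels <- function(z) {
  d <- dim(z)
  zm <- matrix(z, d[1] * d[2], d[3])
  zm <- zm - apply(zm, 1L, max)
  e <- exp(zm)
  array(e / rowSums(e), d)
}

#' Segment an image with a U-Net model
#'
#' Runs the model and returns the per-pixel softmax probabilities and the
#' argmax class masks (background / core / penumbra).
#'
#' @param model a segmentation-task [UNetModel-class].
#' @param img a [WindowedImage-class] with the model's input channel count
#'   and a side length divisible by 2^(depth-1).
#' @return list with `probs` (H x W x 3 array), `core` and `penumbra`
#'   logical masks.
#' @export
segmentImage <- function(model, img) {
  stopifnot(is(model, "UNetModel"), is(img, "WindowedImage"))
  if (model@config$task != "segmentation") stop("model is not a segmentation model")
  fw <- .unetForward(model, img@values, needCache = FALSE)
  p <- .softmaxChannels(fw$out)
  cls <- apply(p, c(1, 2), which.max)
  list(probs = p, core = cls == 2L, penumbra = cls == 3L)
}
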