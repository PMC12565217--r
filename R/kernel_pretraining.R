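## Pretraining of the skip-convolution U-Net and extraction of its skip
## kernels into the KernelBank that drives the pretrained-kernel filter
## block. After bank assembly the kernels are frozen; only the combination
## logits are trained further.

## Gradient of the soft-Dice segmentation loss at the network logits.
#' @keywords internal
.diceLossGrad <- function(logits, coreMask, penMask, eps = 1) {
  p <- .softmaxChannels(logits)
  t2 <- coreMask * 1; t3 <- penMask * 1
  N2 <- 2 * sum(p[, , 2] * t2) + eps; D2 <- sum(p[, , 2]) + sum(t2) + eps
  N3 <- 2 * sum(p[, , 3] * t3) + eps; D3 <- sum(p[, , 3]) + sum(t3) + eps
  loss <- 1 - 0.5 * (N2 / D2 + N3 / D3)
  dP <- array(0, dim(p))
  dP[, , 2] <- -0.5 * (2 * t2 * D2 - N2) / D2^2
  dP[, , 3] <- -0.5 * (2 * t3 * D3 - N3) / D3^2
  # softmax backward per pixel
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2], d[3])
  dm <- matrix(dP, d[1] * d[2], d[3])
  dZ <- array(pm * (dm - rowSums(dm * pm)), d)
  list(loss = loss, dLogits = dZ)
}

#' @keywords internal
.sampleToTensors <- function(sample, inputSize, inCh, useDegraded = FALSE) {
  src <- if (useDegraded && is(sample@degraded, "WindowedImage"))
    sample@degraded else sample@clean
  v <- imageValues(src, drop = TRUE)
  if (!is.matrix(v)) v <- v[, , 1L]
  if (nrow(v) != inputSize)
    v <- .resizePlane(v, inputSize, inputSize, "bilinear")
  x <- if (inCh == 3L) array(c(v, v, v), c(inputSize, inputSize, 3L))
       else array(v, c(inputSize, inputSize, 1L))
  rs <- function(m) if (nrow(m) == inputSize) m
                    else .resizePlane(m * 1, inputSize, inputSize, "nearest") > 0.5
  list(x = x, core = rs(sample@coreMask), pen = rs(sample@penumbraMask),
       cleanPlane = {
    cv <- imageValues(sample@clean, drop = TRUE)
    if (!is.matrix(cv)) cv <- cv[, , 1L]
    if (nrow(cv) != inputSize) cv <- .resizePlane(cv, inputSize, inputSize, "bilinear")
    cv
  })
}

#' Pretrain a skip-convolution U-Net on phantom samples
#'
#' Trains with AdamW (decoupled weight decay 0.05, betas 0.9/0.99, cosine
#' learning-rate decay from `lr`) on the configured task: soft Dice loss on
#' the core/penumbra masks for "segmentation", mean-absolute-error
#' reconstruction of the clean slice for "reconstruction". In reconstruction
#' mode, samples carrying a degraded twin are used as a *denoising*
#' autoencoder (degraded in, clean out) -- this is what gives the skip
#' convolutions genuine enhancement structure worth extracting; without
#' twins (or with `denoise = FALSE`) it is a plain autoencoder. Samples are
#' processed singly in a seeded shuffled order; the run is bit-reproducible
#' from (model, samples, seed).
#'
#' @param model a [UNetModel-class] from [buildSkipUNet()].
#' @param samples non-empty list of [PhantomSample-class].
#' @param epochs training epochs (default 50, the duration at which feature
#'   learning plateaus; tests and desk runs use far fewer).
#' @param seed integer seed for the shuffling.
#' @param lr initial learning rate (default 1e-4).
#' @param inputSize working resolution; must be divisible by
#'   2^(depth-1) (default 64).
#' @param denoise in reconstruction mode, feed the degraded twin as input
#'   when present (default TRUE).
#' @return list with the trained `model` and `history` (per-epoch mean loss).
#' @export
pretrainSkipUNet <- function(model, samples, epochs = 50L, seed = 1L,
                             lr = 1e-4, inputSize = 64L, denoise = TRUE) {
  if (length(samples) == 0L) stop("empty sample set")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("'epochs' must be at least 1")
  cfg <- model@config
  if (inputSize %% 2L^(cfg$depth - 1L) != 0L)
    stop("'inputSize' must be divisible by 2^(depth-1)")
  tensors <- lapply(samples, .sampleToTensors, inputSize = inputSize,
                    inCh = cfg$inCh,
                    useDegraded = cfg$task == "reconstruction" && isTRUE(denoise))
  params <- model@weights
  st <- .adamwInit(params)
  total <- epochs * length(tensors)
  step <- 0L
  set.seed(as.integer(seed))
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(tensors))
    losses <- numeric(length(ord))
    for (ii in seq_along(ord)) {
      tn <- tensors[[ord[ii]]]
      m <- new("UNetModel", config = cfg, weights = params)
      fw <- .unetForward(m, tn$x, needCache = TRUE)
      if (cfg$task == "segmentation") {
        lg <- .diceLossGrad(fw$out, tn$core, tn$pen)
        loss <- lg$loss; dOut <- lg$dLogits
      } else {
        target <- array(tn$cleanPlane, dim(fw$out))
        diff <- fw$out - target
        loss <- mean(abs(diff))
        dOut <- sign(diff) / length(diff)
      }
      bw <- .unetBackward(m, fw$cache, dOut)
      params <- .adamwStep(params, bw$grads, st, cosineLR(lr, step, total))
      step <- step + 1L
      losses[ii] <- loss
    }
    history[ep] <- mean(losses)
  }
  list(model = new("UNetModel", config = cfg, weights = params),
       history = history)
}

#' Extract multi-scale kernels from a skip-convolution U-Net
#'
#' Reduces each requested skip convolution's weight tensor
#' (k x k x C x C) to one spatial k x k kernel and assembles a
#' [KernelBank-class] with zero logits (equal weights). Reduction rules:
#' "channel-mean" (mean over input/output channels, default),
#' "first-channel" (weight slice (,,1,1)), "frobenius-top-1" (the channel
#' pair with the largest Frobenius norm). Each kernel then receives a
#' unit-DC centre-tap correction (the centre weight is shifted so the kernel
#' sums to one), making the filter block exactly constant-preserving; the
#' rule is recorded in the bank manifest. Extraction is read-only: the
#' source model is not modified.
#'
#' @param model a [UNetModel-class] with skip convolutions.
#' @param sizes kernel sizes to extract (default 5, 7, 11).
#' @param reduction reduction rule, see above.
#' @return a [KernelBank-class] with one kernel per requested size.
#' @export
extractKernels <- function(model, sizes = c(5L, 7L, 11L),
                           reduction = c("channel-mean", "first-channel",
                                         "frobenius-top-1")) {
  reduction <- match.arg(reduction)
  have <- model@config$skipKernelSizes
  if (is.null(have)) stop("model has no skip convolutions")
  kernels <- lapply(sizes, function(sz) {
    i <- match(sz, have)
    if (is.na(i)) stop("no skip convolution of size ", sz, " in the model")
    W <- model@weights[[paste0("skip", i, "_W")]]
    k <- switch(reduction,
      "channel-mean" = apply(W, c(1, 2), mean),
      "first-channel" = W[, , 1, 1],
      "frobenius-top-1" = {
        nc <- dim(W)[3]; mc <- dim(W)[4]
        best <- c(1L, 1L); bn <- -Inf
        for (a in seq_len(nc)) for (b in seq_len(mc)) {
          fn <- sum(W[, , a, b]^2)
          if (fn > bn) { bn <- fn; best <- c(a, b) }
        }
        W[, , best[1], best[2]]
      })
    ctr <- (dim(W)[1] + 1L) %/% 2L
    k[ctr, ctr] <- k[ctr, ctr] + (1 - sum(k))   # unit DC gain
    k
  })
  kernelBank(kernels, alphaLogits = rep(0, length(kernels)),
             manifest = list(reduction = reduction, dcCorrected = TRUE,
                             sizes = as.integer(sizes),
                             sourceTask = model@config$task,
                             sourceDepth = model@config$depth))
}

#' Save a kernel bank as JSON
#' @param bank a [KernelBank-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
saveKernelBank <- function(bank, path) {
  obj <- list(kernels = lapply(bank@kernels, function(k)
                list(size = nrow(k), data = as.numeric(k))),
              alphaLogits = bank@alphaLogits, manifest = bank@manifest)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a kernel bank saved by [saveKernelBank()]
#' @param path JSON path.
#' @return a [KernelBank-class].
#' @export
loadKernelBank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kernels <- lapply(seq_len(nrow(obj$kernels)), function(i)
    matrix(obj$kernels$data[[i]], obj$kernels$size[i], obj$kernels$size[i]))
  kernelBank(kernels, alphaLogits = obj$alphaLogits,
             manifest = as.list(obj$manifest))
}
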