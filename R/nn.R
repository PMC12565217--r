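## Minimal neural-network layer set: zero-padded strided convolution,
## batch normalisation (per-image spatial statistics), ReLU, 2x2 max pool,
## nearest-neighbour x2 upsampling, fully connected layers, and AdamW with
## cosine learning-rate decay. Forward passes return caches consumed by the
## matching backward passes; everything is shift-and-add / BLAS, single
## threaded and deterministic.

#' @keywords internal
.heInit <- function(dims, fanIn) array(stats::rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)

#' @keywords internal
.zeroPad <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

#' @keywords internal
.convF <- function(x, W, b, stride = 1L, pad = 1L) {
  k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  xp <- .zeroPad(x, pad)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (Wd + 2L * pad - k) %/% stride + 1L
  Y <- matrix(rep(b, each = Ho * Wo), Ho * Wo, Cout)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    ri <- seq.int(di, by = stride, length.out = Ho)
    ci <- seq.int(dj, by = stride, length.out = Wo)
    sub <- matrix(xp[ri, ci, , drop = FALSE], Ho * Wo, Cin)
    Y <- Y + sub %*% matrix(W[di, dj, , , drop = FALSE], Cin, Cout)
  }
  array(Y, c(Ho, Wo, Cout))
}

#' @keywords internal
.convB <- function(x, W, stride, pad, dY) {
  k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  Ho <- dim(dY)[1]; Wo <- dim(dY)[2]
  xp <- .zeroPad(x, pad)
  dxp <- array(0, dim(xp))
  dYm <- matrix(dY, Ho * Wo, Cout)
  dW <- array(0, dim(W))
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    ri <- seq.int(di, by = stride, length.out = Ho)
    ci <- seq.int(dj, by = stride, length.out = Wo)
    sub <- matrix(xp[ri, ci, , drop = FALSE], Ho * Wo, Cin)
    dW[di, dj, , ] <- crossprod(sub, dYm)
    dsub <- dYm %*% t(matrix(W[di, dj, , , drop = FALSE], Cin, Cout))
    dxp[ri, ci, ] <- dxp[ri, ci, , drop = FALSE] + array(dsub, c(Ho, Wo, Cin))
  }
  dx <- dxp[pad + seq_len(H), pad + seq_len(Wd), , drop = FALSE]
  list(dx = dx, dW = dW, db = colSums(dYm))
}

## Batch normalisation with streaming (EMA) statistics. The training loops
## process images singly; normalising each image by its *own* spatial
## statistics (instance norm) would erase exactly the global brightness and
## contrast information the parameter heads must read, so both training and
## inference normalise with the running dataset statistics, which training
## updates by exponential moving average from the per-image spatial moments.
## The statistics are treated as constants in the backward pass (the
## frozen-statistics convention).
#' @keywords internal
.bnF <- function(x, gamma, beta, running, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  }
  inv <- 1 / sqrt(running$var + eps)
  xhat <- sweep(sweep(xm, 2, running$mean), 2, inv, `*`)
  ym <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(ym, d), cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d),
       running = running)
}

#' @keywords internal
.bnB <- function(cache, dY) {
  d <- cache$d; n <- d[1] * d[2]
  dym <- matrix(dY, n, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  # statistics are constants, so the input gradient is a pure rescale
  dxm <- sweep(dym, 2, cache$gamma * cache$inv, `*`)
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

#' @keywords internal
.reluF <- function(x) pmax(x, 0)

#' @keywords internal
.reluB <- function(x, dY) dY * (x > 0)

#' @keywords internal
.pool2F <- function(x) {
  d <- dim(x)
  o1 <- seq.int(1L, d[1], 2L); o2 <- seq.int(2L, d[1], 2L)
  p1 <- seq.int(1L, d[2], 2L); p2 <- seq.int(2L, d[2], 2L)
  a <- x[o1, p1, , drop = FALSE]; b <- x[o2, p1, , drop = FALSE]
  cc <- x[o1, p2, , drop = FALSE]; dd <- x[o2, p2, , drop = FALSE]
  out <- pmax(pmax(a, b), pmax(cc, dd))
  list(y = out, cache = list(a = a, b = b, cc = cc, dd = dd, out = out, d = d))
}

#' @keywords internal
.pool2B <- function(cache, dY) {
  d <- cache$d
  ia <- cache$a == cache$out
  ib <- (cache$b == cache$out) & !ia
  ic <- (cache$cc == cache$out) & !ia & !ib
  id <- !ia & !ib & !ic
  dx <- array(0, d)
  o1 <- seq.int(1L, d[1], 2L); o2 <- seq.int(2L, d[1], 2L)
  p1 <- seq.int(1L, d[2], 2L); p2 <- seq.int(2L, d[2], 2L)
  dx[o1, p1, ] <- dY * ia
  dx[o2, p1, ] <- dY * ib
  dx[o1, p2, ] <- dY * ic
  dx[o2, p2, ] <- dY * id
  dx
}

#' @keywords internal
.up2F <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  x[ri, ci, , drop = FALSE]
}

#' @keywords internal
.up2B <- function(dY) {
  d <- dim(dY)
  o1 <- seq.int(1L, d[1], 2L); o2 <- seq.int(2L, d[1], 2L)
  p1 <- seq.int(1L, d[2], 2L); p2 <- seq.int(2L, d[2], 2L)
  dY[o1, p1, , drop = FALSE] + dY[o2, p1, , drop = FALSE] +
    dY[o1, p2, , drop = FALSE] + dY[o2, p2, , drop = FALSE]
}

## ---- optimiser -----------------------------------------------------------

#' Cosine learning-rate schedule
#'
#' lr(t) = lr0 * 0.5 * (1 + cos(pi t / T)); lr(0) = lr0 and lr(T) = 0.
#'
#' @param lr0 initial learning rate.
#' @param t current step (0-based).
#' @param total total number of steps T.
#' @return learning rate at step t.
#' @export
cosineLR <- function(lr0, t, total) lr0 * 0.5 * (1 + cos(pi * t / total))

## AdamW state is an environment holding first/second moments per parameter
## name; `step` applies one decoupled-weight-decay update to a parameter list.
#' @keywords internal
.adamwInit <- function(params, beta1 = 0.9, beta2 = 0.99, eps = 1e-8,
                       weightDecay = 0.05) {
  st <- new.env(parent = emptyenv())
  zeroLike <- function(p) if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  st$m <- lapply(params, zeroLike)
  st$v <- lapply(params, zeroLike)
  st$t <- 0L
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$wd <- weightDecay
  st
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Parameters whose names match `noDecay` (batchnorm scales/shifts, biases)
## are exempt from weight decay, the usual convention.
#' @keywords internal
.adamwStep <- function(params, grads, st, lr,
                       noDecay = "(_b$|_beta$|_gamma$)") {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    upd <- (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + st$eps)
    wd <- if (grepl(noDecay, nm)) 0 else st$wd
    params[[nm]] <- params[[nm]] - lr * (upd + wd * params[[nm]])
  }
  params
}
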