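## Low-level image numerics shared by the filter bank, the networks and the
## synthetic-data generator. Images are numeric arrays H x W (matrix) or
## H x W x C; all code is vectorised shift-and-add / BLAS, no compiled code.

#' @keywords internal
.asPlaneList <- function(x) {
  if (is.matrix(x)) return(list(x))
  stopifnot(length(dim(x)) == 3L)
  lapply(seq_len(dim(x)[3L]), function(c) x[, , c])
}

#' @keywords internal
.fromPlaneList <- function(planes) {
  if (length(planes) == 1L) return(planes[[1L]])
  array(unlist(planes, use.names = FALSE),
        dim = c(dim(planes[[1L]]), length(planes)))
}

## Reflect ("mirror without repeating the edge"? -- we use symmetric
## half-sample reflection, edge pixel repeated across the border: the
## convention of scipy's mode="reflect"/"symmetric" family; constraint that
## matters here is only that constants stay constant and no zeros leak in).
#' @keywords internal
.reflectIndex <- function(n, pad) {
  idx <- seq.int(1L - pad, n + pad)
  # symmetric reflection: ... 2 1 | 1 2 ... n | n n-1 ...
  period <- 2L * n
  idx <- ((idx - 1L) %% period + period) %% period  # 0-based mod
  ifelse(idx < n, idx + 1L, period - idx)
}

#' @keywords internal
.padReflect <- function(m, pad) {
  m[.reflectIndex(nrow(m), pad), .reflectIndex(ncol(m), pad), drop = FALSE]
}

## Dense 2-D convolution (correlation) of one plane with a (2a+1) x (2b+1)
## kernel under reflect padding, via shift-and-add.
#' @keywords internal
.convolvePlane <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  pad <- max(ph, pw)
  mp <- .padReflect(m, pad)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  r0 <- pad - ph; c0 <- pad - pw
  for (i in seq_len(kh)) {
    wrow <- kernel[i, ]
    nz <- which(wrow != 0)
    for (j in nz) {
      out <- out + wrow[j] *
        mp[(r0 + i):(r0 + i + h - 1L), (c0 + j):(c0 + j + w - 1L)]
    }
  }
  out
}

#' Convolve an image with a kernel under reflect padding
#'
#' Plain spatial convolution (cross-correlation with the kernel as given;
#' all kernels in this package are centre-symmetric so the distinction is
#' moot) applied per channel. Border handling is symmetric reflection so
#' constant images are mapped to constant images whenever the kernel sums
#' to one.
#'
#' @param x numeric matrix or H x W x C array in any range.
#' @param kernel odd-sized numeric matrix.
#' @return object of the same shape as `x`.
#' @export
convolveReflect <- function(x, kernel) {
  kernel <- as.matrix(kernel)
  stopifnot(is.numeric(kernel), all(is.finite(kernel)))
  planes <- lapply(.asPlaneList(x), .convolvePlane, kernel = kernel)
  .fromPlaneList(planes)
}

## Separable convolution with a 1-D kernel applied along rows then columns.
#' @keywords internal
.convolveSeparablePlane <- function(m, k1d) {
  n <- length(k1d)
  stopifnot(n %% 2L == 1L)
  pad <- (n - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  # vertical pass
  mp <- m[.reflectIndex(h, pad), , drop = FALSE]
  v <- matrix(0, h, w)
  for (i in seq_len(n)) v <- v + k1d[i] * mp[i:(i + h - 1L), , drop = FALSE]
  # horizontal pass
  vp <- v[, .reflectIndex(w, pad), drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_len(n)) out <- out + k1d[j] * vp[, j:(j + w - 1L), drop = FALSE]
  out
}

#' @keywords internal
.convolveSeparable <- function(x, k1d) {
  .fromPlaneList(lapply(.asPlaneList(x), .convolveSeparablePlane, k1d = k1d))
}

## Exact 3x3 median via a 19-comparator sorting network evaluated with
## vectorised pmin/pmax over the nine shifted copies of the plane.
#' @keywords internal
.medianPlane3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  mp <- .padReflect(m, 1L)
  p <- vector("list", 9L)
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    k <- k + 1L
    p[[k]] <- mp[(1L + di):(h + di), (1L + dj):(w + dj), drop = FALSE]
  }
  sort3 <- function(a, b, c) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    list(lo = pmin(lo, c), mid = pmax(lo, pmin(hi, c)), hi = pmax(hi, c))
  }
  # median of 9 = med3( max of column mins, med of column meds, min of column maxs )
  c1 <- sort3(p[[1]], p[[2]], p[[3]])
  c2 <- sort3(p[[4]], p[[5]], p[[6]])
  c3 <- sort3(p[[7]], p[[8]], p[[9]])
  q1 <- pmax(pmax(c1$lo, c2$lo), c3$lo)
  q2 <- sort3(c1$mid, c2$mid, c3$mid)$mid
  q3 <- pmin(pmin(c1$hi, c2$hi), c3$hi)
  sort3(q1, q2, q3)$mid
}

## General odd-window exact median (used for window > 3); apply-based, slow
## but only exercised at small sizes.
#' @keywords internal
.medianPlane <- function(m, window) {
  if (window == 3L) return(.medianPlane3(m))
  pad <- (window - 1L) %/% 2L
  mp <- .padReflect(m, pad)
  h <- nrow(m); w <- ncol(m)
  stack <- matrix(0, h * w, window * window)
  k <- 0L
  for (di in seq_len(window)) for (dj in seq_len(window)) {
    k <- k + 1L
    stack[, k] <- mp[(di):(di + h - 1L), (dj):(dj + w - 1L)]
  }
  matrix(apply(stack, 1L, stats::median), h, w)
}

## ---- bilinear / nearest resampling --------------------------------------

## Sample plane m at fractional (row, col) positions with bilinear weights;
## coordinates are 1-based pixel centres, clamped to the image.
#' @keywords internal
.bilinearSamplePlane <- function(m, rows, cols) {
  h <- nrow(m); w <- ncol(m)
  r <- pmin(pmax(rows, 1), h)
  c <- pmin(pmax(cols, 1), w)
  r0 <- pmin(floor(r), h - 1L); r1 <- r0 + 1
  c0 <- pmin(floor(c), w - 1L); c1 <- c0 + 1
  fr <- r - r0; fc <- c - c0
  base0 <- (c0 - 1) * h; base1 <- (c1 - 1) * h
  v <- (1 - fr) * (1 - fc) * m[r0 + base0] + fr * (1 - fc) * m[r1 + base0] +
       (1 - fr) * fc * m[r0 + base1] + fr * fc * m[r1 + base1]
  matrix(v, nrow = attr(rows, "outH"), ncol = attr(rows, "outW"))
}

#' @keywords internal
.nearestSamplePlane <- function(m, rows, cols) {
  h <- nrow(m); w <- ncol(m)
  r <- pmin(pmax(round(rows), 1), h)
  c <- pmin(pmax(round(cols), 1), w)
  matrix(m[r + (c - 1) * h], nrow = attr(rows, "outH"), ncol = attr(rows, "outW"))
}

## Half-pixel-centred source coordinates for resizing to outH x outW.
#' @keywords internal
.resizeCoords <- function(h, w, outH, outW) {
  sr <- h / outH; sc <- w / outW
  rr <- (seq_len(outH) - 0.5) * sr + 0.5
  cc <- (seq_len(outW) - 0.5) * sc + 0.5
  rows <- rep(rr, times = outW); cols <- rep(cc, each = outH)
  attr(rows, "outH") <- outH; attr(rows, "outW") <- outW
  list(rows = rows, cols = cols)
}

#' @keywords internal
.resizePlane <- function(m, outH, outW, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  co <- .resizeCoords(nrow(m), ncol(m), outH, outW)
  if (method == "bilinear") .bilinearSamplePlane(m, co$rows, co$cols)
  else .nearestSamplePlane(m, co$rows, co$cols)
}

## Rotate plane by `deg` degrees (counter-clockwise) about the image centre,
## keeping the frame; out-of-frame samples take the fill value.
#' @keywords internal
.rotatePlane <- function(m, deg, method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  h <- nrow(m); w <- ncol(m)
  th <- deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- rep(seq_len(h), times = w) - cy
  cc <- rep(seq_len(w), each = h) - cx
  # inverse map: output (r,c) samples input rotated by -theta
  sr <- cos(th) * rr - sin(th) * cc + cy
  sc <- sin(th) * rr + cos(th) * cc + cx
  inside <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  attr(sr, "outH") <- h; attr(sr, "outW") <- w
  out <- if (method == "bilinear") .bilinearSamplePlane(m, sr, sc)
         else .nearestSamplePlane(m, sr, sc)
  out[!inside] <- fill
  out
}

#' @keywords internal
.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @keywords internal
.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
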