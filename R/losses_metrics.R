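## Training objectives (SSIM + L1 restoration loss, soft Dice loss) and the
## segmentation metric suite: slice-wise Dice/Jaccard, volumetric Dice/IoU,
## Hausdorff / HD95 / ASSD in millimetres, and the trimap F-measure.

## ---- SSIM ----------------------------------------------------------------

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over the image with the standard 11 x 11 Gaussian window
#' (sigma = 1.5) and stabilisers C1 = 0.01^2, C2 = 0.03^2 on the unit
#' dynamic range; multi-channel images average the per-channel maps (for the
#' triplicated CT representation all channels are identical, so the value is
#' invariant to triplication). Symmetric in its arguments.
#'
#' @param a,b [WindowedImage-class] objects or numeric arrays of one shape.
#' @return scalar in [-1, 1]; 1 iff the images are identical.
#' @export
ssim <- function(a, b) {
  av <- if (is(a, "WindowedImage")) a@values else a
  bv <- if (is(b, "WindowedImage")) b@values else b
  if (is.matrix(av)) av <- array(av, c(dim(av), 1L))
  if (is.matrix(bv)) bv <- array(bv, c(dim(bv), 1L))
  if (!all(dim(av) == dim(bv))) stop("ssim: images must share a shape")
  mean(vapply(seq_len(dim(av)[3L]), function(c)
    .ssimPlane(av[, , c], bv[, , c]), numeric(1)))
}

#' @keywords internal
.ssimPlane <- function(x, y, C1 = 0.01^2, C2 = 0.03^2) {
  g <- .gaussian1d(1.5, 5L)
  mu_x <- .convolveSeparablePlane(x, g)
  mu_y <- .convolveSeparablePlane(y, g)
  sxx <- .convolveSeparablePlane(x * x, g) - mu_x^2
  syy <- .convolveSeparablePlane(y * y, g) - mu_y^2
  sxy <- .convolveSeparablePlane(x * y, g) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Restoration loss: weighted (1 - SSIM) + mean absolute error
#'
#' The preprocessing training objective: `wSSIM * (1 - ssim(Ie, Igt)) +
#' wL1 * mean(|Ie - Igt|)`. The L1 term is the mean so the weights are
#' resolution independent. Zero iff the images coincide (up to the SSIM
#' stabilisers).
#'
#' @param Ie,Igt enhanced and target images ([WindowedImage-class] or array).
#' @param wSSIM,wL1 non-negative term weights (default 1 each).
#' @return non-negative scalar.
#' @export
preprocLoss <- function(Ie, Igt, wSSIM = 1, wL1 = 1) {
  if (wSSIM < 0 || wL1 < 0) stop("loss weights must be non-negative")
  ev <- if (is(Ie, "WindowedImage")) Ie@values else Ie
  gv <- if (is(Igt, "WindowedImage")) Igt@values else Igt
  if (!all((dim(ev) %||% length(ev)) == (dim(gv) %||% length(gv))))
    stop("loss: images must share a shape")
  wSSIM * (1 - ssim(ev, gv)) + wL1 * mean(abs(ev - gv))
}

## ---- Dice loss -----------------------------------------------------------

#' Soft Dice loss over the lesion classes
#'
#' 1 minus the mean soft Dice of the core and penumbra channels, with the
#' smoothing constant `eps` added to numerator and denominator (so an empty
#' prediction of an empty target scores a perfect 0). Background is
#' excluded, as only the lesion classes carry the supervision signal.
#'
#' @param predCore,predPenumbra numeric matrices of soft predictions in [0, 1].
#' @param coreMask,penumbraMask logical target matrices.
#' @param eps smoothing constant (default 1).
#' @return scalar in [0, 1].
#' @export
diceLoss <- function(predCore, predPenumbra, coreMask, penumbraMask, eps = 1) {
  if (is.null(predCore) || is.null(predPenumbra)) stop("both lesion channels are required")
  soft <- function(p, t) (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  1 - mean(c(soft(predCore, coreMask), soft(predPenumbra, penumbraMask)))
}

## ---- overlap metrics -----------------------------------------------------

#' @keywords internal
.checkBinary <- function(m) {
  if (is.logical(m)) return(m)
  if (!all(m %in% c(0, 1))) stop("masks must be binary")
  m > 0
}

#' Slice-wise Dice coefficient
#'
#' 2|P intersect T| / (|P| + |T|); by convention 1 when both masks are empty
#' (a lesion-free slice predicted clean is correct).
#'
#' @param pred,truth binary masks of one shape.
#' @return scalar in [0, 1].
#' @export
dice2d <- function(pred, truth) {
  p <- .checkBinary(pred); t <- .checkBinary(truth)
  stopifnot(all(dim(p) == dim(t)))
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Slice-wise Jaccard (IoU) coefficient
#'
#' |P intersect T| / |P union T|; 1 when both masks are empty.
#'
#' @inheritParams dice2d
#' @return scalar in [0, 1].
#' @export
jaccard2d <- function(pred, truth) {
  p <- .checkBinary(pred); t <- .checkBinary(truth)
  stopifnot(all(dim(p) == dim(t)))
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p & t) / u
}

#' @keywords internal
.asSliceList <- function(x) {
  if (is.list(x)) return(lapply(x, .checkBinary))
  if (length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[3L]), function(i) .checkBinary(x[, , i])))
  list(.checkBinary(x))
}

#' Volumetric Dice coefficient
#'
#' Per-slice intersections and sizes are summed across the stacked volume
#' before forming the ratio (equivalently, voxel-wise 3-D Dice). Overlap
#' metrics are spacing free.
#'
#' @param pred,truth binary volumes: 3-D arrays or lists of slice masks.
#' @return scalar in [0, 1]; 1 when both volumes are empty.
#' @export
dice3d <- function(pred, truth) {
  p <- .asSliceList(pred); t <- .asSliceList(truth)
  if (length(p) != length(t)) stop("volumes must have the same slice count")
  inter <- sum(mapply(function(a, b) sum(a & b), p, t))
  size <- sum(vapply(p, sum, numeric(1))) + sum(vapply(t, sum, numeric(1)))
  if (size == 0) return(1)
  2 * inter / size
}

#' Volumetric IoU
#' @inheritParams dice3d
#' @return scalar in [0, 1]; 1 when both volumes are empty.
#' @export
iou3d <- function(pred, truth) {
  p <- .asSliceList(pred); t <- .asSliceList(truth)
  if (length(p) != length(t)) stop("volumes must have the same slice count")
  inter <- sum(mapply(function(a, b) sum(a & b), p, t))
  uni <- sum(mapply(function(a, b) sum(a | b), p, t))
  if (uni == 0) return(1)
  inter / uni
}

## ---- surface distances ---------------------------------------------------

#' Boundary voxels of a binary mask
#'
#' A mask voxel is boundary if any face neighbour (4-connectivity in 2-D,
#' 6-connectivity in 3-D) is background, or it touches the array edge.
#'
#' @param mask logical matrix or 3-D array.
#' @return integer matrix of boundary voxel coordinates (one row per voxel).
#' @export
maskBoundary <- function(mask) {
  m <- .checkBinary(mask)
  if (is.matrix(m)) {
    d <- dim(m)
    pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
    pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
    core <- pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
            pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
    which(m & !core, arr.ind = TRUE)
  } else {
    d <- dim(m)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
    i <- 2:(d[1] + 1L); j <- 2:(d[2] + 1L); k <- 2:(d[3] + 1L)
    core <- pad[i - 1L, j, k] & pad[i + 1L, j, k] &
            pad[i, j - 1L, k] & pad[i, j + 1L, k] &
            pad[i, j, k - 1L] & pad[i, j, k + 1L]
    which(m & !core, arr.ind = TRUE)
  }
}

## Directed nearest-neighbour distances from each row of A to the set B
## (physical coordinates), brute force with chunking.
#' @keywords internal
.directedDistances <- function(A, B, chunk = 2048L) {
  nA <- nrow(A)
  out <- numeric(nA)
  bt <- t(B)
  b2 <- colSums(bt^2)
  for (s in seq.int(1L, nA, by = chunk)) {
    e <- min(s + chunk - 1L, nA)
    Ac <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, `+`) - 2 * Ac %*% bt
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Hausdorff-family surface distances in millimetres
#'
#' Computes, between two non-empty point sets (or the boundary voxels of two
#' binary masks, scaled by `spacing`):
#' `max` -- the classical symmetric Hausdorff distance, the larger of the two
#' directed supremum distances; `hd95` -- the 95th-percentile variant,
#' symmetrised by the maximum of the two directed percentiles; `assd` -- the
#' average symmetric surface distance, the mean of all directed
#' nearest-neighbour distances pooled over both directions.
#'
#' @param pred,truth numeric point matrices (one point per row) or binary
#'   masks (matrix / 3-D array), in which case boundary voxels are used.
#' @param mode "max", "hd95" or "assd".
#' @param spacing physical size of one voxel step per axis, mm
#'   (default unit spacing).
#' @return distance in mm.
#' @export
hausdorffDistance <- function(pred, truth, mode = c("max", "hd95", "assd"),
                              spacing = NULL) {
  mode <- match.arg(mode)
  # logical matrices and 3-D arrays are masks (boundary voxels are used);
  # numeric 2-D matrices are taken literally as point sets
  toPts <- function(x) {
    if (is.logical(x) || length(dim(x)) == 3L) maskBoundary(x) else as.matrix(x)
  }
  A <- toPts(pred); B <- toPts(truth)
  if (is.null(dim(A))) A <- matrix(A, ncol = length(A))
  if (is.null(dim(B))) B <- matrix(B, ncol = length(B))
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("undefined distance: empty point set")
  if (!is.null(spacing)) {
    sp <- rep_len(spacing, ncol(A))
    A <- sweep(A, 2L, sp, `*`)
    B <- sweep(B, 2L, sp, `*`)
  }
  dAB <- .directedDistances(A, B)
  dBA <- .directedDistances(B, A)
  switch(mode,
    max = max(max(dAB), max(dBA)),
    hd95 = max(stats::quantile(dAB, 0.95, names = FALSE),
               stats::quantile(dBA, 0.95, names = FALSE)),
    assd = (sum(dAB) + sum(dBA)) / (length(dAB) + length(dBA)))
}

## ---- trimap F-measure ----------------------------------------------------

#' Trimap F-measure (boundary-band F-score)
#'
#' F-measure of the prediction against the truth restricted to pixels whose
#' Euclidean distance to the true mask boundary is at most `band` pixels;
#' emphasises edge fidelity. With a band wider than the image it reduces to
#' the global F-measure.
#'
#' @param pred,truth binary masks of one shape; the truth must be non-empty.
#' @param band band half-width in pixels (default 5).
#' @return scalar in [0, 1].
#' @export
trimapF <- function(pred, truth, band = 5) {
  p <- .checkBinary(pred); t <- .checkBinary(truth)
  stopifnot(all(dim(p) == dim(t)))
  if (!any(t)) stop("undefined trimap F: empty truth mask")
  bd <- maskBoundary(t)
  d <- dim(t)
  px <- cbind(rep(seq_len(d[1]), times = d[2]), rep(seq_len(d[2]), each = d[1]))
  dist <- .directedDistances(px, bd)
  inBand <- matrix(dist <= band, d[1], d[2])
  tp <- sum(p & t & inBand)
  fp <- sum(p & !t & inBand)
  fn <- sum(!p & t & inBand)
  if (tp == 0 && fp == 0 && fn == 0) return(1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

## ---- aggregate report ----------------------------------------------------

#' Segmentation metric report
#'
#' Per-class slice-wise and volumetric overlap metrics plus surface
#' distances, as produced by [evaluateSegmentation()].
#'
#' @slot perSlice data.frame of slice-wise Dice/Jaccard per class.
#' @slot summary data.frame of per-class volumetric metrics.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @slot skipped named integer vector: slices skipped per distance metric
#'   because a surface was empty.
#' @export
setClass("MetricReport",
  representation(perSlice = "data.frame", summary = "data.frame",
                 spacing = "numeric", skipped = "integer"))

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport (spacing", paste(object@spacing, collapse = " x "), "mm)\n")
  print(object@summary, row.names = FALSE)
  if (any(object@skipped > 0))
    cat("skipped (empty surface):",
        paste(names(object@skipped), object@skipped, sep = "=", collapse = ", "), "\n")
})

#' Evaluate a predicted segmentation against ground truth
#'
#' Computes, per lesion class (core, penumbra): slice-wise Dice and Jaccard,
#' volumetric Dice and IoU, and -- whenever both surfaces are non-empty --
#' 3-D Hausdorff, HD95 and ASSD in mm, plus the mean slice-wise trimap
#' F-measure. Distance metrics use the physical voxel spacing; overlap
#' metrics are spacing free.
#'
#' @param pred,truth lists with logical 3-D arrays `core` and `penumbra`.
#' @param spacing voxel spacing (row, column, slice) in mm,
#'   default c(0.5, 0.5, 5).
#' @param band trimap band half-width in pixels (default 5).
#' @return a [MetricReport-class].
#' @export
evaluateSegmentation <- function(pred, truth, spacing = c(0.5, 0.5, 5), band = 5) {
  classes <- c("core", "penumbra")
  perSlice <- do.call(rbind, lapply(classes, function(cl) {
    p <- pred[[cl]]; t <- truth[[cl]]
    stopifnot(all(dim(p) == dim(t)))
    ns <- dim(p)[3L]
    data.frame(class = cl, slice = seq_len(ns),
               dice = vapply(seq_len(ns), function(i) dice2d(p[, , i], t[, , i]), numeric(1)),
               jaccard = vapply(seq_len(ns), function(i) jaccard2d(p[, , i], t[, , i]), numeric(1)))
  }))
  skipped <- c(distance = 0L, trimap = 0L)
  rows <- lapply(classes, function(cl) {
    p <- pred[[cl]]; t <- truth[[cl]]
    hd <- hd95 <- assd <- NA_real_
    if (any(p) && any(t)) {
      hd <- hausdorffDistance(p, t, "max", spacing)
      hd95 <- hausdorffDistance(p, t, "hd95", spacing)
      assd <- hausdorffDistance(p, t, "assd", spacing)
    } else skipped["distance"] <<- skipped["distance"] + 1L
    tf <- NA_real_
    tfv <- c()
    for (i in seq_len(dim(t)[3L])) {
      if (any(t[, , i])) tfv <- c(tfv, trimapF(p[, , i], t[, , i], band))
      else skipped["trimap"] <<- skipped["trimap"] + 1L
    }
    if (length(tfv)) tf <- mean(tfv)
    data.frame(class = cl, dice3d = dice3d(p, t), iou3d = iou3d(p, t),
               hd = hd, hd95 = hd95, assd = assd, trimapF = tf)
  })
  new("MetricReport", perSlice = perSlice, summary = do.call(rbind, rows),
      spacing = as.numeric(rep_len(spacing, 3L)), skipped = skipped)
}
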