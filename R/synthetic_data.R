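## Procedural brain-CT-like phantoms with core/penumbra masks, uniform
## phantoms for artifact-safety controls, and the paired soft-degradation
## dataset that stands in for clinical slices so the whole pipeline is
## testable without downloads. The phantoms make no claim of anatomical
## realism; they carry the statistical structure the method assumes: a
## bright skull ring, smooth textured parenchyma, and a subtle hypodense
## lesion with a graded penumbra around a darker core.

#' Degradation specification for soft augmentation
#'
#' Ranges of the mild photometric/geometric degradations used to build
#' paired training data: Gaussian blur sigma in [0, 0.20] px, additive
#' Gaussian noise with variance drawn from [10, 50] on the 8-bit scale
#' (intensity-domain sd = sqrt(var)/255), centre crop to a side in
#' [400, 512] (applied fractionally for other image sizes) followed by a
#' resize back, rotation in [-10, 10] degrees, and brightness/contrast
#' adjustment within a +-20% limit, in the augmentation-library convention:
#' brightness adds delta times the full intensity range, contrast rescales
#' about mid-gray by 1 + delta. Each transform fires independently with its
#' probability.
#'
#' @param blurSigmaRange,noiseVarRange,cropRange,rotationRange,bcRange
#'   numeric length-2 ranges as above.
#' @param probs named numeric vector of per-transform probabilities in
#'   [0, 1] (names: blur, noise, crop, rotation, brightness, contrast).
#' @return list, the validated specification.
#' @export
degradationSpec <- function(blurSigmaRange = c(0, 0.20),
                            noiseVarRange = c(10, 50),
                            cropRange = c(400, 512),
                            rotationRange = c(-10, 10),
                            bcRange = c(-0.20, 0.20),
                            probs = c(blur = 0.5, noise = 0.5, crop = 0.5,
                                      rotation = 0.5, brightness = 0.5,
                                      contrast = 0.5)) {
  stopifnot(all(probs >= 0 & probs <= 1))
  list(blurSigmaRange = blurSigmaRange, noiseVarRange = noiseVarRange,
       cropRange = cropRange, rotationRange = rotationRange,
       bcRange = bcRange, probs = probs)
}

#' @keywords internal
.ellipseR2 <- function(rows, cols, cy, cx, a, b, theta = 0) {
  dr <- rows - cy; dc <- cols - cx
  u <- cos(theta) * dr + sin(theta) * dc
  v <- -sin(theta) * dr + cos(theta) * dc
  (u / a)^2 + (v / b)^2
}

#' Generate a brain-like CT phantom with lesion masks
#'
#' Draws (deterministically from `seed`) an elliptical skull ring, a smooth
#' mildly textured brain interior with ventricles, and, with probability
#' `lesionProb`, a hypodense lesion: a graded penumbra blob containing a
#' darker core blob. The core mask is contained in the lesion and disjoint
#' from the penumbra mask; both lie inside the brain.
#'
#' @param seed integer seed; the sample is fully determined by it.
#' @param size image side length in pixels, at least 128 (default 512).
#' @param lesionProb probability of drawing a lesion (default 0.85).
#' @return a [PhantomSample-class] with the degraded slot unset.
#' @export
generatePhantom <- function(seed, size = 512L, lesionProb = 0.85) {
  size <- as.integer(size)
  if (size < 128L) stop("'size' must be at least 128")
  set.seed(as.integer(seed))
  rows <- matrix(rep(seq_len(size), times = size), size, size)
  cols <- matrix(rep(seq_len(size), each = size), size, size)
  cy <- size * stats::runif(1, 0.48, 0.52)
  cx <- size * stats::runif(1, 0.48, 0.52)
  a <- size * stats::runif(1, 0.33, 0.38)
  b <- size * stats::runif(1, 0.38, 0.43)
  th <- stats::runif(1, -0.25, 0.25)
  r2 <- .ellipseR2(rows, cols, cy, cx, a, b, th)
  re <- sqrt(r2)
  brain <- re <= 1
  # smooth low-frequency parenchymal texture: coarse noise upsampled
  coarse <- matrix(stats::rnorm(32 * 32, 0, 1), 32, 32)
  texture <- .resizePlane(coarse, size, size, "bilinear") * 0.02
  img <- matrix(0.02, size, size)               # air
  img[brain] <- 0.40 + texture[brain]
  # skull ring with soft edges
  ring <- .clip01((1.10 - re) / 0.04) * .clip01((re - 1) / 0.02)
  img <- img * (1 - ring) + 0.95 * ring
  # ventricles: two small dark ellipses flanking the centre
  for (s in c(-1, 1)) {
    vr2 <- .ellipseR2(rows, cols, cy, cx + s * 0.08 * size,
                      0.10 * a, 0.22 * b, th + s * 0.3)
    w <- .clip01((1 - sqrt(vr2)) / 0.25)
    img <- img - 0.10 * w
  }
  coreMask <- matrix(FALSE, size, size)
  penMask <- matrix(FALSE, size, size)
  params <- list(lesion = FALSE)
  if (stats::runif(1) < lesionProb) {
    # lesion centre well inside the brain
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0.15, 0.55)
    ly <- cy + rad * a * 0.9 * sin(ang)
    lx <- cx + rad * b * 0.9 * cos(ang)
    pa <- size * stats::runif(1, 0.06, 0.11)
    pb <- size * stats::runif(1, 0.06, 0.11)
    lth <- stats::runif(1, -pi / 2, pi / 2)
    rp <- sqrt(.ellipseR2(rows, cols, ly, lx, pa, pb, lth))
    cScale <- stats::runif(1, 0.40, 0.60)
    rc <- rp / cScale
    # graded hypodensity: subtle in the penumbra, deeper in the core
    wPen <- .clip01((1 - rp) / 0.35)
    wCore <- .clip01((1 - rc) / 0.35)
    img <- img - (0.045 * wPen + 0.05 * wCore) * brain
    penEll <- (rp <= 1) & brain
    coreMask <- (rc <= 1) & brain
    penMask <- penEll & !coreMask
    params <- list(lesion = TRUE, centre = c(ly, lx), axes = c(pa, pb),
                   coreScale = cScale)
  }
  new("PhantomSample",
      clean = windowedImage(.clip01(img)), degraded = NULL,
      coreMask = coreMask, penumbraMask = penMask,
      seed = as.integer(seed), paramsApplied = params)
}

#' Generate a uniform-intensity phantom
#'
#' A constant image, the negative control of the artifact-safety protocol:
#' a preprocessing pipeline that cannot hallucinate structure must map it to
#' a (near-)constant image.
#'
#' @param value constant intensity in [0, 1].
#' @param size side length in pixels (default 512).
#' @return a single-channel [WindowedImage-class].
#' @export
generateUniformPhantom <- function(value, size = 512L) {
  if (!is.finite(value) || value < 0 || value > 1) stop("'value' must lie in [0, 1]")
  windowedImage(matrix(value, size, size))
}

#' Soft-augment a clean image into a degraded twin
#'
#' Applies a randomly drawn subset of the degradations in `spec` (fully
#' determined by `seed`). Geometric transforms (rotation, centre-crop +
#' resize) are applied to the target and the masks as well -- a restoration
#' target must stay spatially aligned with its input -- unless
#' `geometryToTarget = FALSE`, in which case the untransformed clean image
#' is returned as target. Masks are resampled with nearest neighbour so the
#' one-hot structure survives; a geometric draw that changes the core area
#' by more than 25% is redrawn (count recorded).
#'
#' @param clean a [WindowedImage-class] in [0, 1].
#' @param spec a [degradationSpec()].
#' @param seed integer seed.
#' @param coreMask,penumbraMask optional logical masks to carry through the
#'   geometric transforms.
#' @param geometryToTarget keep target aligned with the degraded input
#'   (default TRUE).
#' @return list with `degraded`, `target` (both [WindowedImage-class]),
#'   `coreMask`, `penumbraMask`, and `paramsApplied`.
#' @export
softAugment <- function(clean, spec = degradationSpec(), seed = 1L,
                        coreMask = NULL, penumbraMask = NULL,
                        geometryToTarget = TRUE) {
  stopifnot(is(clean, "WindowedImage"))
  set.seed(as.integer(seed))
  v <- imageValues(clean, drop = TRUE)
  if (!is.matrix(v)) v <- v[, , 1L]
  size <- nrow(v)
  p <- spec$probs
  fire <- stats::runif(6) < p[c("blur", "noise", "crop", "rotation",
                                "brightness", "contrast")]
  names(fire) <- c("blur", "noise", "crop", "rotation", "brightness", "contrast")
  params <- list(applied = names(fire)[fire], redraws = 0L)

  ## geometric draw (with lesion-preservation guard)
  drawGeom <- function() list(
    angle = stats::runif(1, spec$rotationRange[1], spec$rotationRange[2]),
    cropFrac = stats::runif(1, spec$cropRange[1] / 512, spec$cropRange[2] / 512))
  applyGeom <- function(m, g, method) {
    out <- m
    if (fire["rotation"])
      out <- .rotatePlane(out, g$angle, method,
                          fill = if (is.logical(m)) 0 else min(m))
    if (fire["crop"]) {
      s <- max(8L, round(size * g$cropFrac))
      o <- (size - s) %/% 2L
      out <- .resizePlane(out[(o + 1L):(o + s), (o + 1L):(o + s), drop = FALSE],
                          size, size, method)
    }
    out
  }
  g <- drawGeom()
  if (!is.null(coreMask) && sum(coreMask) > 0 && (fire["rotation"] || fire["crop"])) {
    for (try in 1:10) {
      newCore <- applyGeom(coreMask * 1, g, "nearest") > 0.5
      if (abs(sum(newCore) - sum(coreMask)) <= 0.25 * sum(coreMask)) break
      g <- drawGeom()
      params$redraws <- params$redraws + 1L
    }
  }
  geomV <- applyGeom(v, g, "bilinear")
  if (fire["rotation"]) params$rotationDeg <- g$angle
  if (fire["crop"]) params$cropSide <- round(size * g$cropFrac)

  ## photometric degradations on the geometric frame
  deg <- geomV
  if (fire["blur"]) {
    s <- stats::runif(1, max(spec$blurSigmaRange[1], 1e-3), spec$blurSigmaRange[2])
    deg <- .convolveSeparablePlane(deg, .gaussian1d(s, 2L))
    params$blurSigma <- s
  }
  if (fire["noise"]) {
    varDraw <- stats::runif(1, spec$noiseVarRange[1], spec$noiseVarRange[2])
    deg <- deg + matrix(stats::rnorm(length(deg), 0, sqrt(varDraw) / 255),
                        nrow(deg), ncol(deg))
    params$noiseVar <- varDraw
  }
  if (fire["brightness"]) {
    db <- stats::runif(1, spec$bcRange[1], spec$bcRange[2])
    # additive delta as a fraction of the full intensity range (the
    # augmentation-library convention for a brightness limit of 0.2)
    deg <- deg + db
    params$brightnessDelta <- db
  }
  if (fire["contrast"]) {
    dc <- stats::runif(1, spec$bcRange[1], spec$bcRange[2])
    deg <- (deg - 0.5) * (1 + dc) + 0.5
    params$contrastDelta <- dc
  }
  deg <- .clip01(deg)

  target <- if (geometryToTarget) .clip01(geomV) else v
  outCore <- coreMask; outPen <- penumbraMask
  if (!is.null(coreMask) && geometryToTarget && (fire["rotation"] || fire["crop"])) {
    outCore <- applyGeom(coreMask * 1, g, "nearest") > 0.5
    outPen <- applyGeom(penumbraMask * 1, g, "nearest") > 0.5
    outPen <- outPen & !outCore
  }
  list(degraded = windowedImage(deg), target = windowedImage(target),
       coreMask = outCore, penumbraMask = outPen, paramsApplied = params)
}

#' Build a paired degraded/clean phantom dataset
#'
#' Generates `n` phantoms and their soft-degraded twins: the degraded image
#' is the training source, the (geometry-aligned) clean image the target,
#' and the masks are carried through the geometric transforms with nearest
#' neighbour resampling. Byte-reproducible from `seed`.
#'
#' @param n number of samples, at least 1.
#' @param seed integer master seed.
#' @param spec a [degradationSpec()].
#' @param size phantom side length (default 512).
#' @param lesionProb per-sample lesion probability (default 0.85).
#' @param geometryToTarget see [softAugment()].
#' @return list of [PhantomSample-class] with the degraded slot set.
#' @export
buildPairedDataset <- function(n, seed = 1L, spec = degradationSpec(),
                               size = 512L, lesionProb = 0.85,
                               geometryToTarget = TRUE) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1")
  lapply(seq_len(n), function(i) {
    si <- (as.integer(seed) + i * 7919L) %% .Machine$integer.max
    ph <- generatePhantom(si, size = size, lesionProb = lesionProb)
    aug <- softAugment(ph@clean, spec, seed = si + 1L,
                       coreMask = ph@coreMask, penumbraMask = ph@penumbraMask,
                       geometryToTarget = geometryToTarget)
    new("PhantomSample", clean = aug$target, degraded = aug$degraded,
        coreMask = if (is.null(aug$coreMask)) ph@coreMask else aug$coreMask,
        penumbraMask = if (is.null(aug$penumbraMask)) ph@penumbraMask else aug$penumbraMask,
        seed = si, paramsApplied = aug$paramsApplied)
  })
}
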