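test_that("phantoms are deterministic and structurally valid", {
  a <- generatePhantom(101, 128)
  b <- generatePhantom(101, 128)
  expect_identical(imageValues(a@clean), imageValues(b@clean))
  expect_identical(a@coreMask, b@coreMask)
  expect_false(identical(imageValues(a@clean),
                         imageValues(generatePhantom(102, 128)@clean)))
  expect_error(generatePhantom(1, 64), "at least 128")
})

test_that("lesion masks are disjoint and confined to brain tissue", {
  for (seed in 1:25) {
    ph <- generatePhantom(seed, 128, lesionProb = 1)
    expect_false(any(ph@coreMask & ph@penumbraMask))
    expect_gt(sum(ph@coreMask), 0)
    v <- imageValues(ph@clean, drop = TRUE)
    # lesion pixels sit on parenchyma, not air or skull
    lesion <- ph@coreMask | ph@penumbraMask
    expect_true(all(v[lesion] > 0.1 & v[lesion] < 0.8))
  }
  free <- generatePhantom(7, 128, lesionProb = 0)
  expect_equal(sum(free@coreMask), 0)
  expect_equal(sum(free@penumbraMask), 0)
})

test_that("uniform phantoms are constant and self-similar", {
  ph <- generateUniformPhantom(0.5, 64)
  expect_true(all(imageValues(ph) == 0.5))
  expect_equal(ssim(ph, ph), 1)
  expect_error(generateUniformPhantom(1.2, 64), "\\[0, 1\\]")
  # any unit-sum kernel transform leaves it constant
  out <- applyKernelCombo(ph, analyticBank())
  expect_lt(max(abs(imageValues(out) - 0.5)), 1e-12)
})

test_that("a no-op degradation draw returns the clean image", {
  ph <- generatePhantom(11, 128)
  spec <- degradationSpec(probs = c(blur = 0, noise = 0, crop = 0,
                                    rotation = 0, brightness = 0, contrast = 0))
  aug <- softAugment(ph@clean, spec, seed = 5)
  expect_identical(imageValues(aug$degraded), imageValues(ph@clean))
  expect_length(aug$paramsApplied$applied, 0L)
})

test_that("every drawn degradation parameter respects its declared range", {
  spec <- degradationSpec()
  ph <- generatePhantom(13, 128)
  for (seed in 1:200) {
    aug <- softAugment(ph@clean, spec, seed = seed)
    pa <- aug$paramsApplied
    if (!is.null(pa$blurSigma))
      expect_true(pa$blurSigma >= 0 && pa$blurSigma <= 0.20)
    if (!is.null(pa$noiseVar))
      expect_true(pa$noiseVar >= 10 && pa$noiseVar <= 50)
    if (!is.null(pa$cropSide))
      expect_true(pa$cropSide >= 128 * 400 / 512 - 1 && pa$cropSide <= 128)
    if (!is.null(pa$rotationDeg))
      expect_true(abs(pa$rotationDeg) <= 10)
    if (!is.null(pa$brightnessDelta))
      expect_true(abs(pa$brightnessDelta) <= 0.20)
    if (!is.null(pa$contrastDelta))
      expect_true(abs(pa$contrastDelta) <= 0.20)
    # size never changes
    expect_equal(dim(imageValues(aug$degraded))[1:2], c(128L, 128L))
  }
})

test_that("degradation keeps images recognisable but not identical", {
  vals <- vapply(1:40, function(seed) {
    ph <- generatePhantom(2000 + seed, 256)
    aug <- softAugment(ph@clean, degradationSpec(), seed = 3000 + seed)
    s <- ssim(aug$target, aug$degraded)
    # a draw can be a numerical no-op (e.g. sigma ~ 0 blur, full-frame
    # crop); whenever it measurably changed the image, similarity drops
    if (max(abs(imageValues(aug$degraded) - imageValues(aug$target))) > 0)
      expect_lt(s, 1)
    s
  }, numeric(1))
  m <- mean(vals)
  expect_gt(m, 0.6)
  expect_lt(m, 1.0)
})

test_that("masks stay one-hot and lesions survive geometric transforms", {
  spec <- degradationSpec(probs = c(blur = 0, noise = 0, crop = 1,
                                    rotation = 1, brightness = 0, contrast = 0))
  for (seed in 1:15) {
    ph <- generatePhantom(seed, 128, lesionProb = 1)
    aug <- softAugment(ph@clean, spec, seed = 400 + seed,
                       coreMask = ph@coreMask, penumbraMask = ph@penumbraMask)
    expect_type(aug$coreMask, "logical")
    expect_false(any(aug$coreMask & aug$penumbraMask))
    expect_lte(abs(sum(aug$coreMask) - sum(ph@coreMask)), 0.25 * sum(ph@coreMask))
  }
})

test_that("paired datasets are reproducible and validated", {
  d1 <- buildPairedDataset(4, seed = 9, size = 128)
  d2 <- buildPairedDataset(4, seed = 9, size = 128)
  for (i in 1:4) {
    expect_identical(imageValues(d1[[i]]@degraded), imageValues(d2[[i]]@degraded))
    expect_identical(imageValues(d1[[i]]@clean), imageValues(d2[[i]]@clean))
    expect_identical(d1[[i]]@coreMask, d2[[i]]@coreMask)
  }
  expect_error(buildPairedDataset(0), "at least 1")
})
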