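test_that("Gaussian kernel samples match hand evaluation and normalise", {
  k <- gaussianKernel(1, 1)
  # hand evaluation of the centred Gaussian at the nine grid points, then
  # renormalisation: centre weight 0.15915/(0.15915 + 4*0.09653 + 4*0.05855)
  expect_equal(k[2, 2], 0.2042, tolerance = 1e-4)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_error(gaussianKernel(0), "positive")
  expect_error(gaussianKernel(-1), "positive")
  # delta limit
  expect_gt(gaussianKernel(0.01, 2)[3, 3], 0.999)
  # central symmetry on random specs
  for (seed in 1:10) {
    set.seed(seed)
    sig <- runif(1, 0.2, 3); kk <- sample(1:4, 1)
    kern <- gaussianKernel(sig, kk)
    n <- 2 * kk + 1
    expect_equal(kern, kern[n:1, n:1])
  }
})

test_that("Gaussian blur matches a dense brute-force convolution", {
  img <- windowedImage(randomImage(21, 9))
  out <- gaussianBlur(img, 1.3, k = 2)
  oracle <- bruteConv(imageValues(img, drop = TRUE), gaussianKernel(1.3, 2))
  expect_lt(max(abs(imageValues(out, drop = TRUE) - oracle)), 1e-6)
  # separable and dense paths agree
  dense <- gaussianBlur(img, 1.3, k = 2, separable = FALSE)
  expect_lt(max(abs(imageValues(out) - imageValues(dense))), 1e-6)
  # constants are fixed points
  cimg <- windowedImage(matrix(0.42, 12, 12))
  expect_true(all(abs(imageValues(gaussianBlur(cimg, 2)) - 0.42) < 1e-12))
})

test_that("sharpness normaliser is affine in q with the printed sums", {
  spec <- sharpnessSpec()
  expect_equal(sum(spec$K), -256)
  expect_equal(sum(spec$M), 21)
  expect_equal(spec$nu(0), -256)
  expect_equal(spec$nu(1), -235)
  expect_equal(spec$nu(-1), -277)
  # K and M symmetric under transpose and 90-degree rotation
  expect_equal(spec$K, t(spec$K))
  expect_equal(spec$M, t(spec$M))
  expect_equal(spec$K, spec$K[5:1, 5:1])
  for (q in c(-1, -0.5, 0, 0.5, 1))
    expect_equal(sum((spec$K + spec$M * q) / spec$nu(q)), 1, tolerance = 1e-12)
})

test_that("sharpness filter matches the brute-force oracle and fixes constants", {
  img <- windowedImage(randomImage(22, 10))
  spec <- sharpnessSpec()
  for (q in c(-0.7, 0, 0.4)) {
    out <- applySharpness(img, q)
    oracle <- bruteConv(imageValues(img, drop = TRUE),
                        (spec$K + spec$M * q) / spec$nu(q))
    expect_lt(max(abs(imageValues(out, drop = TRUE) - oracle)), 1e-6)
  }
  cimg <- windowedImage(matrix(0.6, 11, 11))
  expect_true(all(abs(imageValues(applySharpness(cimg, 0.8)) - 0.6) < 1e-12))
  expect_error(applySharpness(img, 1.5), "\\[-1, 1\\]")
  # per-channel q on a triplicated image acts channel-wise
  t3 <- triplicateChannels(img)
  out3 <- applySharpness(t3, c(-0.5, 0, 0.5))
  expect_equal(imageValues(out3)[, , 2],
               imageValues(applySharpness(img, 0), drop = TRUE))
})

test_that("contrast filter scales about mid-gray as specified", {
  img <- windowedImage(matrix(0.75, 3, 3))
  expect_equal(imageValues(applyContrast(img, 0.5), drop = TRUE)[1, 1], 1.0)
  expect_equal(imageValues(applyContrast(img, 0.5, literal = TRUE), drop = TRUE)[1, 1], 0.5)
  # identity at r = 0 in default mode
  r0 <- applyContrast(windowedImage(randomImage(4, 8)), 0)
  expect_equal(imageValues(r0), imageValues(windowedImage(randomImage(4, 8))))
  expect_error(applyContrast(img, 1), "\\[-1, 1\\)")
  # order preserving for any valid r; bijection on [0,1] for r <= 0
  set.seed(6); x <- sort(runif(20))
  for (r in c(-0.9, -0.2, 0.3, 0.8)) {
    y <- imageValues(applyContrast(windowedImage(matrix(x, 1)), r), drop = TRUE)
    expect_true(all(diff(as.numeric(y)) > 0))
  }
})

test_that("brightness filter is a pure additive shift", {
  img <- windowedImage(matrix(0.4, 2, 2))
  expect_equal(imageValues(applyBrightness(img, 0.2), drop = TRUE)[1, 1], 0.6)
  expect_equal(imageValues(applyBrightness(img, 0)), imageValues(img))
  # values may exceed 1 before the pipeline clip
  hot <- applyBrightness(windowedImage(matrix(0.95, 2, 2)), 0.2)
  expect_equal(imageValues(hot, drop = TRUE)[1, 1], 1.15)
})

test_that("median filter computes exact order statistics", {
  m <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1, 1), 3, 3)
  out <- applyMedian(windowedImage(m))
  expect_equal(imageValues(out, drop = TRUE)[2, 2], 1)   # 5th of 9 sorted
  salt <- matrix(0.2, 7, 7); salt[4, 4] <- 1
  expect_equal(imageValues(applyMedian(windowedImage(salt)), drop = TRUE)[4, 4], 0.2)
  cimg <- windowedImage(matrix(0.33, 6, 6))
  expect_equal(imageValues(applyMedian(cimg)), imageValues(cimg))
  expect_error(applyMedian(windowedImage(m), 4), "odd")
  # 3x3 sorting network and 5x5 general path both match the oracle
  img <- randomImage(33, 10)
  expect_equal(imageValues(applyMedian(windowedImage(img), 3), drop = TRUE),
               bruteMedian(img, 3))
  expect_equal(imageValues(applyMedian(windowedImage(img), 5), drop = TRUE),
               bruteMedian(img, 5))
})

test_that("kernel combination is a softmax-weighted convolution mixture", {
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  img <- windowedImage(randomImage(7, 8))
  b1 <- kernelBank(list(delta))
  expect_equal(imageValues(applyKernelCombo(img, b1)), imageValues(img))
  # two identical kernels collapse to one regardless of logits
  g <- gaussianKernel(1, 2)
  b2 <- kernelBank(list(g, g), alphaLogits = c(3, -1))
  expect_equal(imageValues(applyKernelCombo(img, b2)),
               imageValues(applyKernelCombo(img, kernelBank(list(g)))),
               tolerance = 1e-12)
  expect_equal(bankAlphas(kernelBank(list(g, g, g))), rep(1 / 3, 3))
  expect_error(kernelBank(list()), "at least one")
  # alphas sum to one even for extreme logits
  bx <- kernelBank(list(g, g, g), alphaLogits = c(50, -50, 0))
  expect_lt(abs(sum(bankAlphas(bx)) - 1), 1e-9)
})

test_that("residuals vanish at neutral parameters and on constants", {
  img <- windowedImage(randomImage(8, 10))
  expect_true(all(filterResidual("brightness", img, list(b = 0)) == 0))
  expect_true(all(filterResidual("contrast", img, list(r = 0)) == 0))
  cimg <- windowedImage(matrix(0.5, 9, 9))
  expect_lt(max(abs(filterResidual("gaussian blur", cimg, list(sigma = 1)))), 1e-12)
  expect_lt(max(abs(filterResidual("median filter", cimg))), 1e-12)
  expect_lt(max(abs(filterResidual("sharpen", cimg, list(q = 0.5)))), 1e-12)
  expect_error(filterResidual("no such filter", img), "unknown filter")
})

test_that("filters are deterministic: identical input gives identical output", {
  img <- windowedImage(randomImage(12, 12))
  a <- applySharpness(img, 0.3)
  b <- applySharpness(img, 0.3)
  expect_identical(imageValues(a), imageValues(b))
  expect_identical(imageValues(gaussianBlur(img, 0.9)),
                   imageValues(gaussianBlur(img, 0.9)))
})
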