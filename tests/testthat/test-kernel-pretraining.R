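test_that("skip U-Nets are built with the configured skip convolutions", {
  m <- buildSkipUNet(seed = 1)
  w <- m@weights
  expect_equal(dim(w$skip1_W)[1:2], c(5L, 5L))
  expect_equal(dim(w$skip2_W)[1:2], c(7L, 7L))
  expect_equal(dim(w$skip3_W)[1:2], c(11L, 11L))
  expect_error(skipUNetConfig(skipKernelSizes = c(4, 7)), "odd")
  expect_error(skipUNetConfig(depth = 2), "at least 3")
  # depth-3 mirror: two decoder levels, one per pooled stage
  m3 <- buildSkipUNet(skipUNetConfig(depth = 3, skipKernelSizes = c(5, 7)), seed = 1)
  expect_true(all(c("dec1_W", "dec2_W") %in% names(m3@weights)))
  expect_false("dec3_W" %in% names(m3@weights))
  # identical seeds give identical initialisation
  expect_identical(buildSkipUNet(seed = 4)@weights, buildSkipUNet(seed = 4)@weights)
})

test_that("pretraining reduces the loss and is seed-reproducible", {
  phs <- lapply(1:8, function(i) generatePhantom(600 + i, 128, lesionProb = 1))
  m <- buildSkipUNet(skipUNetConfig(depth = 4, baseWidth = 3), seed = 2)
  fit <- pretrainSkipUNet(m, phs, epochs = 3, seed = 2, inputSize = 32)
  expect_length(fit$history, 3L)
  expect_lt(fit$history[3], fit$history[1])
  fit2 <- pretrainSkipUNet(m, phs, epochs = 3, seed = 2, inputSize = 32)
  expect_identical(fit$history, fit2$history)
  # degenerate run: one sample, one epoch
  tiny <- pretrainSkipUNet(m, phs[1], epochs = 1, seed = 1, inputSize = 32)
  expect_length(tiny$history, 1L)
  expect_error(pretrainSkipUNet(m, list(), epochs = 1), "empty")
})

test_that("reconstruction task trains under the L1 objective", {
  phs <- lapply(1:6, function(i) generatePhantom(700 + i, 128))
  m <- buildSkipUNet(skipUNetConfig(depth = 3, baseWidth = 3,
                                    skipKernelSizes = c(5, 7),
                                    task = "reconstruction"), seed = 3)
  fit <- pretrainSkipUNet(m, phs, epochs = 3, seed = 3, inputSize = 32)
  expect_lt(fit$history[3], fit$history[1])
})

test_that("kernel extraction is read-only and produces a valid bank", {
  m <- buildSkipUNet(seed = 5)
  before <- serialize(m@weights, NULL)
  bank <- extractKernels(m)
  expect_identical(serialize(m@weights, NULL), before)
  expect_length(bankKernels(bank), 3L)
  expect_equal(vapply(bankKernels(bank), nrow, integer(1)), c(5L, 7L, 11L))
  expect_equal(bankAlphas(bank), rep(1 / 3, 3))
  expect_true(all(vapply(bankKernels(bank), function(k) all(is.finite(k)), logical(1))))
  # DC correction makes every kernel sum to one
  expect_true(all(abs(vapply(bankKernels(bank), sum, numeric(1)) - 1) < 1e-12))
  expect_error(extractKernels(m, sizes = 9), "no skip convolution")
  expect_error(extractKernels(buildToySegmenter(1)), "no skip convolutions")
  # alternative reductions also yield the requested shapes
  for (red in c("first-channel", "frobenius-top-1")) {
    b2 <- extractKernels(m, reduction = red)
    expect_equal(vapply(bankKernels(b2), nrow, integer(1)), c(5L, 7L, 11L))
    expect_equal(b2@manifest$reduction, red)
  }
})

test_that("softmax weights sum to one for any logits", {
  g <- gaussianKernel(1, 2)
  for (lg in list(c(0, 0, 0), c(50, -50, 0), c(-50, -50, -50), rnorm(3, 0, 10))) {
    bank <- kernelBank(list(g, g, g), alphaLogits = lg)
    expect_lt(abs(sum(bankAlphas(bank)) - 1), 1e-9)
  }
})

test_that("kernel banks round-trip through JSON", {
  m <- buildSkipUNet(seed = 6)
  bank <- extractKernels(m)
  path <- tempfile(fileext = ".json")
  saveKernelBank(bank, path)
  back <- loadKernelBank(path)
  for (i in 1:3)
    expect_equal(bankKernels(back)[[i]], bankKernels(bank)[[i]], tolerance = 1e-12)
  expect_equal(back@manifest$reduction, "channel-mean")
})
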