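test_that("zero gains make the pipeline a bit-exact identity", {
  pipe <- smallPipeline(gains = rep(0, 4))
  gen <- buildGenerator(pipe$generator, seed = 2)
  for (seed in 1:5) {
    img <- randomWindowed3(seed, 32)
    out <- enhance(img, gen, pipe)
    expect_identical(imageValues(out), imageValues(img))
  }
})

test_that("neutral parameters leave the image unchanged where defined", {
  # sharpness and the kernel combination have no identity point, so their
  # gains are zeroed; brightness/contrast neutrality is parametric
  pipe <- smallPipeline(gains = c(0, 1, 0, 1))
  np <- neutralParams(pipe)
  expect_equal(np$brightness$b, 0)
  expect_equal(np$contrast$r, 0)
  expect_setequal(attr(np, "flagged"), c("sharpen", "CB 5x5+7x7+11x11"))
  img <- randomWindowed3(9, 32)
  out <- enhanceWithParams(img, np, pipe)
  expect_identical(imageValues(out), imageValues(img))
})

test_that("outputs are clipped to the unit range", {
  pipe <- smallPipeline()
  img <- randomWindowed3(3, 32)
  params <- list(cb = list(logits = c(0, 0, 0)), brightness = list(b = 0.9),
                 sharpen = list(q = c(1, 1, 1)), contrast = list(r = 0.8))
  out <- enhanceWithParams(img, params, pipe)
  v <- imageValues(out)
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
  expect_gt(max(v), 0.99)   # the huge brightness shift saturates pixels
})

test_that("the kernel-combination filter requires a bank", {
  expect_error(pipelineConfig(bank = NULL), "requires 'bank'")
  expect_error(pipelineConfig(filters = c("brightness", "nonexistent")),
               "unknown filter")
  expect_error(pipelineConfig(filters = "brightness", gains = c(1, 1)),
               "one gain per filter")
})

test_that("parameters predicted at low resolution transfer across scales", {
  # a smooth synthetic slice enhanced at full resolution, then downscaled,
  # agrees with enhancing the downscaled copy directly
  ph <- generatePhantom(31, 256)
  img <- triplicateChannels(ph@clean)
  pipe <- smallPipeline(inputSize = 64L)
  gen <- buildGenerator(pipe$generator, seed = 4)
  set.seed(10)
  gen@weights$fc2_W <- array(rnorm(length(gen@weights$fc2_W), 0, 0.2),
                             dim(gen@weights$fc2_W))
  small <- downscaleImage(img, 64L)
  params <- predictParams(gen, small)
  full <- enhanceWithParams(img, params, pipe)
  direct <- enhanceWithParams(small, params, pipe)
  mae <- mean(abs(imageValues(downscaleImage(full, 64L)) - imageValues(direct)))
  expect_lt(mae, 0.02)
})

test_that("constant inputs never gain structure, for any generator", {
  pipe <- smallPipeline()
  gen <- buildGenerator(pipe$generator, seed = 6)
  set.seed(20)
  gen@weights$fc2_W <- array(rnorm(length(gen@weights$fc2_W), 0, 1),
                             dim(gen@weights$fc2_W))   # wild random head
  for (v in c(0.1, 0.5, 0.9)) {
    ph <- triplicateChannels(generateUniformPhantom(v, 32))
    out <- enhance(ph, gen, pipe)
    expect_lt(max(imageValues(out)) - min(imageValues(out)), 1e-9)
  }
})

test_that("predicted blur below threshold is skipped as identity", {
  pipe <- pipelineConfig(filters = c("gaussian blur"), bank = NULL,
                         generator = generatorConfig(
                           inputSize = 32L,
                           headSpec = data.frame(filter = "blur", count = 1L,
                                                 range = "unit")))
  img <- randomWindowed3(17, 32)
  out <- enhanceWithParams(img, list(blur = list(sigma = 0)), pipe)
  expect_identical(imageValues(out), imageValues(img))
  out2 <- enhanceWithParams(img, list(blur = list(sigma = 1.5)), pipe)
  expect_false(identical(imageValues(out2), imageValues(img)))
})
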