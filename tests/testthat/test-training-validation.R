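# Small-scale training harness checks: schedules, determinism, freeze
# contracts and the artifact-safety protocol. All runs use tiny sizes (32 px,
# a handful of pairs) -- they probe mechanisms, not performance.

tinyTrainSet <- function(n = 6, seed = 55) buildPairedDataset(n, seed = seed, size = 128)

test_that("the cosine schedule hits its endpoints exactly", {
  expect_equal(cosineLR(1e-4, 0, 100), 1e-4)
  expect_equal(cosineLR(1e-4, 100, 100), 0)
  expect_equal(cosineLR(2e-3, 50, 100), 2e-3 * 0.5)
  t <- 0:20
  lr <- cosineLR(1, t, 20)
  expect_true(all(diff(lr) < 0))
})

test_that("a zero learning rate leaves the loss unchanged across epochs", {
  ds <- tinyTrainSet(4)
  pipe <- smallPipeline()
  gen <- buildGenerator(pipe$generator, seed = 1)
  fit <- pretrainPreprocessor(gen, pipe, ds,
                              cfg = trainConfig(lrInit = 0, seed = 1), epochs = 2)
  expect_equal(fit$history$trainLoss[1], fit$history$trainLoss[2], tolerance = 1e-12)
  expect_identical(fit$gen@weights, gen@weights)
})

test_that("preprocessor pretraining is bit-reproducible from (config, seed)", {
  ds <- tinyTrainSet(4)
  pipe <- smallPipeline()
  gen <- buildGenerator(pipe$generator, seed = 2)
  f1 <- pretrainPreprocessor(gen, pipe, ds[1:3], cfg = trainConfig(seed = 3),
                             valSamples = ds[4], epochs = 2)
  f2 <- pretrainPreprocessor(gen, pipe, ds[1:3], cfg = trainConfig(seed = 3),
                             valSamples = ds[4], epochs = 2)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$gen@weights, f2$gen@weights)
  expect_error(pretrainPreprocessor(gen, pipe, list()), "empty dataset")
})

test_that("joint fine-tuning honours freeze contracts and reproducibility", {
  ds <- tinyTrainSet(4, seed = 66)
  bank <- analyticBank()
  gcfg <- generatorConfig(inputSize = 32L)
  pipe <- pipelineConfig(bank = bank, generator = gcfg)
  gen <- buildGenerator(gcfg, seed = 4)
  seg <- buildToySegmenter(seed = 4, baseWidth = 4)
  ft <- jointFinetune(gen, seg, pipe, ds, cfg = trainConfig(lrJoint = 1e-3, seed = 5),
                      epochs = 1, inputSize = 32, freezeSegmenter = TRUE)
  expect_identical(ft$segmenter@weights, seg@weights)     # frozen segmenter
  expect_false(identical(ft$gen@weights, gen@weights))    # generator moved
  ft2 <- jointFinetune(gen, seg, pipe, ds, cfg = trainConfig(lrJoint = 1e-3, seed = 5),
                       epochs = 1, inputSize = 32, freezeGenerator = TRUE)
  expect_identical(ft2$gen@weights, gen@weights)
  expect_false(identical(ft2$segmenter@weights, seg@weights))
  ft3 <- jointFinetune(gen, seg, pipe, ds, cfg = trainConfig(lrJoint = 1e-3, seed = 5),
                       epochs = 1, inputSize = 32, freezeGenerator = TRUE)
  expect_identical(ft3$segmenter@weights, ft2$segmenter@weights)
  expect_error(jointFinetune(NULL, seg, NULL, ds, epochs = 1, inputSize = 32),
               "requires gen")
})

test_that("the identity pipeline yields a spotless safety report", {
  pipe <- smallPipeline(gains = rep(0, 4))
  gen <- buildGenerator(pipe$generator, seed = 6)
  rep <- artifactSafetyReport(gen, pipe, nPhantoms = 5, size = 32)
  expect_s4_class(rep, "SafetyReport")
  expect_true(all(rep@phantomSsim == 1))
  expect_true(all(rep@maxAbsDiff == 0))
  expect_false(any(rep@flags))
})

test_that("unit-sum kernel banks keep uniform phantoms constant", {
  pipe <- smallPipeline()   # untrained, full gains
  gen <- buildGenerator(pipe$generator, seed = 7)
  rep <- artifactSafetyReport(gen, pipe, nPhantoms = 6, size = 32)
  expect_true(all(rep@phantomStd <= 1e-6))
  expect_false(any(rep@flags))
  # non-lesion inputs are scored too
  ph <- generatePhantom(900, 128, lesionProb = 0)
  rep2 <- artifactSafetyReport(gen, pipe, inputs = list(downscaleImage(ph@clean, 32)),
                               nPhantoms = 2, size = 32)
  expect_true(is.finite(rep2@meanSsimClean))
})

test_that("ablation tables are schema-stable and seed-deterministic", {
  ds <- tinyTrainSet(6, seed = 77)
  pipe <- smallPipeline()
  configs <- list(comboA = pipe, comboB = pipe)
  tab <- runAblation(configs, ds, seeds = c(1, 2), epochs = 1, inputSize = 32)
  expect_equal(nrow(tab), 2L)
  # identical configurations with identical seeds give identical rows
  expect_equal(tab$dice2dPen[1], tab$dice2dPen[2])
  expect_equal(tab$dice3dCore[1], tab$dice3dCore[2])
  expect_true(all(c("config", "dice2dCore", "dice2dPen", "iou2dCore", "iou2dPen",
                    "dice3dCore", "dice3dPen", "iou3dCore", "iou3dPen") %in% names(tab)))
  expect_warning(runAblation(list(only = pipe), ds, seeds = 1, epochs = 1,
                             inputSize = 32), "single config")
  # CSV output is written when requested
  out <- tempfile(fileext = ".csv")
  suppressWarnings(runAblation(list(a = NULL), ds, seeds = 1, epochs = 1,
                               inputSize = 32, outPath = out))
  expect_true(file.exists(out))
})
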