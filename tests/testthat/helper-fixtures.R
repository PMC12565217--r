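# Shared fixtures. The expensive trained states (used by the acceptance
# suite) are built lazily once per test run and cached in this environment.

.fx <- new.env(parent = emptyenv())

# small analytic kernel bank (unit-sum smoothing kernels of the three sizes)
analyticBank <- function() {
  kernelBank(list(gaussianKernel(0.8, 2L), gaussianKernel(1.2, 3L),
                  gaussianKernel(2.0, 5L)),
             manifest = list(reduction = "analytic-test-bank"))
}

smallPipeline <- function(bank = analyticBank(), inputSize = 32L, ...) {
  pipelineConfig(bank = bank,
                 generator = generatorConfig(inputSize = as.integer(inputSize)),
                 ...)
}

randomWindowed3 <- function(seed, size = 32L) {
  set.seed(seed)
  triplicateChannels(windowedImage(matrix(runif(size * size), size, size)))
}

# kernel bank from a skip U-Net pretrained as a denoising autoencoder on
# paired phantoms (degraded in, clean out)
denoisingBank <- function(seed, nPairs = 40L, epochs = 8L) {
  pairs <- buildPairedDataset(nPairs, seed = seed + 500L, size = 256L)
  su <- buildSkipUNet(skipUNetConfig(task = "reconstruction", inCh = 1L),
                      seed = seed)
  fit <- pretrainSkipUNet(su, pairs, epochs = epochs, seed = seed,
                          inputSize = 64L)
  extractKernels(fit$model)
}

# the scaled study conditions shared by the restoration-gain and
# artifact-safety acceptance checks: preprocessor trained on 200 soft-
# degraded phantom pairs (seed 1234, 5 epochs, generator resolution 128)
# against a 40-pair held-out split, with a kernel bank extracted from a
# denoising-pretrained skip-convolution U-Net
trainedPreprocessor <- function() {
  if (!is.null(.fx$trained)) return(.fx$trained)
  seed <- 1234L
  bank <- denoisingBank(seed)
  ds <- buildPairedDataset(240L, seed = seed, size = 512L)
  pipe <- pipelineConfig(bank = bank)
  gen <- buildGenerator(pipe$generator, seed = seed)
  fit <- pretrainPreprocessor(gen, pipe, ds[1:200], cfg = trainConfig(seed = seed),
                              valSamples = ds[201:240], epochs = 5L)
  .fx$trained <- list(fit = fit, pipe = pipe, bank = bank)
  .fx$trained
}

# the toy joint-training setting: everything at 64 px so ten paired-seed
# runs stay affordable
jointSetting <- function() {
  if (!is.null(.fx$joint)) return(.fx$joint)
  seed <- 77L
  bank <- denoisingBank(seed, nPairs = 24L, epochs = 5L)
  gcfg <- generatorConfig(inputSize = 64L)
  pipe <- pipelineConfig(bank = bank, generator = gcfg)
  ds <- buildPairedDataset(72L, seed = seed, size = 256L)
  gen <- buildGenerator(gcfg, seed = seed)
  pre <- pretrainPreprocessor(gen, pipe, ds[1:48], cfg = trainConfig(seed = seed),
                              valSamples = ds[49:56], epochs = 3L)
  .fx$joint <- list(gen = pre$gen, pipe = pipe, train = ds[1:48],
                    test = ds[57:72])
  .fx$joint
}
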