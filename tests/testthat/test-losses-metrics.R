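test_that("SSIM matches closed forms and is symmetric", {
  img <- randomImage(1, 24)
  expect_equal(ssim(img, img), 1)
  # constants: variance terms cancel, luminance term remains
  expect_equal(ssim(matrix(0.5, 16, 16), matrix(0.6, 16, 16)),
               (2 * 0.30 + 1e-4) / (0.25 + 0.36 + 1e-4), tolerance = 1e-9)
  other <- 1 - img
  expect_lt(ssim(img, other), 1)
  expect_equal(ssim(img, other), ssim(other, img))
  # invariant to identical channel triplication
  t3 <- function(m) array(c(m, m, m), c(dim(m), 3))
  expect_equal(ssim(t3(img), t3(other)), ssim(img, other))
  expect_error(ssim(img, randomImage(1, 12)), "share a shape")
})

test_that("restoration loss combines SSIM and mean L1 as specified", {
  img <- randomImage(2, 16)
  expect_equal(preprocLoss(img, img), 0, tolerance = 1e-9)
  a <- matrix(0.2, 16, 16); b <- matrix(0.5, 16, 16)
  expect_equal(preprocLoss(a, b), 0.3 + (1 - ssim(a, b)), tolerance = 1e-9)
  for (seed in 1:10)
    expect_gte(preprocLoss(randomImage(seed, 8), randomImage(seed + 100, 8)), 0)
  expect_error(preprocLoss(a, b, wSSIM = -1), "non-negative")
})

test_that("soft Dice loss follows the eps = 1 smoothing convention", {
  t <- matrix(FALSE, 4, 4); t[1:2, 1:2] <- TRUE
  perfect <- diceLoss(t * 1, t * 1, t, t)
  expect_lt(perfect, 0.2)                 # exactly 0 as eps -> 0
  expect_equal(diceLoss(matrix(0, 4, 4), matrix(0, 4, 4),
                        matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 0)
  # |pred| = |gt| = 4 with overlap 2: 1 - (2*2+1)/(4+4+1) = 4/9
  p <- matrix(FALSE, 4, 4); p[2:3, 2:3] <- TRUE
  tt <- matrix(FALSE, 4, 4); tt[1:2, 2:3] <- TRUE
  expect_equal(diceLoss(p * 1, p * 1, tt, tt), 4 / 9)
})

test_that("slice metrics match the set-arithmetic examples", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(dice2d(a, a), 1)
  expect_equal(jaccard2d(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(dice2d(a, b), 0)
  expect_equal(jaccard2d(a, b), 0)
  p <- matrix(FALSE, 4, 4); p[1:2, 2:3] <- TRUE
  expect_equal(dice2d(p, a), 0.5)          # sizes 4/4, overlap 2
  expect_equal(jaccard2d(p, a), 1 / 3)
  empty <- matrix(FALSE, 4, 4)
  expect_equal(dice2d(empty, empty), 1)
  expect_error(dice2d(matrix(0.5, 2, 2), empty[1:2, 1:2]), "binary")
})

test_that("volumetric metrics sum intersections across slices", {
  sliceA_p <- matrix(FALSE, 4, 4); sliceA_p[1:2, 1:2] <- TRUE
  sliceA_t <- matrix(FALSE, 4, 4); sliceA_t[2:3, 1:2] <- TRUE   # overlap 2
  sliceB_p <- matrix(FALSE, 4, 4); sliceB_p[1, 1:2] <- TRUE
  sliceB_t <- matrix(FALSE, 4, 4); sliceB_t[4, 1:2] <- TRUE     # overlap 0
  expect_equal(dice3d(list(sliceA_p, sliceB_p), list(sliceA_t, sliceB_t)),
               2 * 2 / (6 + 6))
  vol <- array(runif(64) > 0.5, c(4, 4, 4))
  expect_equal(dice3d(vol, vol), 1)
  expect_error(dice3d(list(sliceA_p), list(sliceA_t, sliceB_t)), "slice count")
})

test_that("Dice and Jaccard obey D = 2J/(1+J) on random volumes", {
  for (seed in 1:100) {
    set.seed(seed)
    p <- array(runif(256) > runif(1, 0.3, 0.9), c(8, 8, 4))
    t <- array(runif(256) > runif(1, 0.3, 0.9), c(8, 8, 4))
    J <- iou3d(p, t)
    expect_equal(dice3d(p, t), 2 * J / (1 + J), tolerance = 1e-12)
  }
})

test_that("Hausdorff-family distances match hand values and bounds", {
  A <- matrix(c(0, 0), 1, 2)
  B <- matrix(c(3, 4), 1, 2)
  expect_equal(hausdorffDistance(A, B, "max"), 5)
  expect_equal(hausdorffDistance(A, A, "max"), 0)
  expect_equal(hausdorffDistance(A, A, "hd95"), 0)
  expect_equal(hausdorffDistance(A, A, "assd"), 0)
  expect_error(hausdorffDistance(matrix(numeric(0), 0, 2), B), "undefined")
  # physical spacing scales distances
  m1 <- matrix(FALSE, 6, 6); m1[2, 2] <- TRUE
  m2 <- matrix(FALSE, 6, 6); m2[2, 4] <- TRUE
  expect_equal(hausdorffDistance(m1, m2, "max", spacing = c(1, 0.5)), 1)
  # hd95 never exceeds the max mode; symmetry of max and assd
  for (seed in 1:50) {
    set.seed(seed)
    p <- matrix(runif(64) > 0.6, 8, 8); t <- matrix(runif(64) > 0.6, 8, 8)
    if (!any(p) || !any(t)) next
    expect_lte(hausdorffDistance(p, t, "hd95"),
               hausdorffDistance(p, t, "max") + 1e-12)
    expect_equal(hausdorffDistance(p, t, "max"), hausdorffDistance(t, p, "max"))
    expect_equal(hausdorffDistance(p, t, "assd"), hausdorffDistance(t, p, "assd"))
  }
})

test_that("max-mode Hausdorff agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  for (seed in 1:20) {
    set.seed(seed)
    A <- matrix(runif(20, 0, 10), 10, 2)
    B <- matrix(runif(16, 0, 10), 8, 2)
    expect_equal(hausdorffDistance(A, B, "max"),
                 pracma::hausdorff_dist(A, B), tolerance = 1e-12)
  }
})

test_that("trimap F-measure restricts scoring to the boundary band", {
  t <- matrix(FALSE, 16, 16); t[5:10, 5:10] <- TRUE
  expect_equal(trimapF(t, t), 1)
  # a prediction dilated well beyond the band loses precision inside it
  p <- matrix(FALSE, 16, 16); p[2:14, 2:14] <- TRUE
  expect_lt(trimapF(p, t, band = 2), 1)
  # band wider than the image reduces to the global F-measure
  set.seed(5)
  pr <- matrix(runif(256) > 0.5, 16, 16)
  expect_equal(trimapF(pr, t, band = 100), bruteF(pr, t))
  expect_error(trimapF(pr, matrix(FALSE, 16, 16)), "empty truth")
})

test_that("segmentation reports aggregate per-class metrics", {
  set.seed(8)
  t <- list(core = array(runif(256) > 0.7, c(8, 8, 4)),
            penumbra = array(runif(256) > 0.7, c(8, 8, 4)))
  t$penumbra <- t$penumbra & !t$core
  rep <- evaluateSegmentation(t, t)
  expect_s4_class(rep, "MetricReport")
  expect_equal(rep@summary$dice3d, c(1, 1))
  expect_equal(rep@summary$hd95, c(0, 0))
  expect_equal(nrow(rep@perSlice), 8L)
  expect_true(all(rep@perSlice$dice == 1))
  # empty prediction against empty truth skips distance metrics
  e <- list(core = array(FALSE, c(8, 8, 2)), penumbra = array(FALSE, c(8, 8, 2)))
  rep2 <- evaluateSegmentation(e, e)
  expect_true(all(is.na(rep2@summary$hd95)))
  expect_gt(sum(rep2@skipped), 0)
  expect_equal(rep2@summary$dice3d, c(1, 1))
})
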