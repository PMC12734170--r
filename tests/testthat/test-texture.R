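# texture descriptors, fusion, projections and the model input

test_that("local contrast reproduces hand-computed window variances", {
  # lone bright pixel: mu = 1, sum of squared deviations = 64 + 8
  f <- matrix(0, 3, 3); f[2, 2] <- 9
  expect_equal(localContrast(f, window = 3)[2, 2], 8)
  # binary 5x5 window with 13 ones: population variance p(1-p)
  g <- matrix(0, 5, 5); g[seq_len(13)] <- 1
  expect_equal(localContrast(g, window = 5)[3, 3], (13 / 25) * (12 / 25),
               tolerance = 1e-12)
  expect_equal(localContrast(g, window = 5)[3, 3], 0.2496, tolerance = 1e-12)
  # constant frames have zero variance everywhere
  expect_true(all(localContrast(matrix(4, 8, 8)) == 0))
  # sqrt option returns the windowed standard deviation
  expect_equal(localContrast(g, window = 5, sqrt = TRUE)[3, 3],
               sqrt(0.2496), tolerance = 1e-12)
  expect_error(localContrast(f, window = 4), "odd")
  expect_error(localContrast(f, window = 9), "odd|larger")
})

test_that("local contrast matches the double-loop oracle on random frames", {
  set.seed(21)
  for (i in 1:25) {
    f <- matrix(runif(16 * 16), 16, 16)
    w <- sample(c(3, 5, 7), 1)
    expect_lt(max(abs(localContrast(f, w) - oracleContrast(f, w))), 1e-10)
  }
})

test_that("local entropy reproduces closed-form window values", {
  # constant window: the as-printed formula gives -log2(1 + eps), not 0
  H0 <- localEntropy(matrix(0.5, 7, 7), window = 5, levels = 256)
  expect_true(all(abs(H0) <= 1e-12))
  expect_true(all(H0 <= 0))  # tiny negative floor from eps in the log
  # 25 distinct levels in a 5x5 window: maximal entropy log2(25)
  f <- matrix((0:24) / 25, 5, 5)
  expect_equal(localEntropy(f, window = 5, levels = 25)[3, 3], log2(25),
               tolerance = 1e-6)
  # entropy is bounded by log2(min(levels, window^2))
  set.seed(22)
  g <- matrix(runif(100), 10, 10)
  expect_true(all(localEntropy(g, 5, 256) <= log2(25) + 1e-9))
  expect_true(all(localEntropy(g, 5, 8) <= log2(8) + 1e-9))
  expect_error(localEntropy(g, 5, levels = 1), "levels")
})

test_that("local entropy matches the double-loop oracle on random frames", {
  set.seed(23)
  for (i in 1:25) {
    f <- matrix(runif(16 * 16), 16, 16)
    L <- sample(c(4, 16, 256), 1)
    expect_lt(max(abs(localEntropy(f, 5, L) - oracleEntropy(f, 5, L))), 1e-10)
  }
})

test_that("brightness threshold is the empirical-CDF percentile with a
           strict bright mask", {
  # 1..100 each once: T at the 85th order statistic, 15 strictly brighter
  f <- matrix(1:100, 10, 10)
  bt <- brightnessThreshold(f, 0.85)
  expect_equal(bt$threshold, 85)
  expect_equal(sum(bt$mask), 15)
  # degenerate distribution: T is the constant, mask empty
  bt <- brightnessThreshold(matrix(3, 6, 6), 0.85)
  expect_equal(bt$threshold, 3)
  expect_equal(sum(bt$mask), 0)
  # 90 percent zeros: CDF jumps past q at zero, mask is the bright 10 percent
  g <- matrix(0, 10, 10); g[1:10] <- 255
  bt <- brightnessThreshold(g, 0.85)
  expect_equal(bt$threshold, 0)
  expect_equal(sum(bt$mask), 10)
  expect_true(all(bt$mask[g == 255] == 1))
  expect_error(brightnessThreshold(f, 1), "q must")
})

test_that("quantile property: fraction(I > T) <= 1-q <= fraction(I >= T)", {
  set.seed(24)
  for (i in 1:50) {
    f <- matrix(sample(0:40, 144, TRUE), 12, 12)
    q <- runif(1, 0.05, 0.95)
    T <- brightnessThreshold(f, q)$threshold
    expect_lte(mean(f > T), 1 - q + 1e-12)
    expect_gte(mean(f >= T), 1 - q - 1e-12)
  }
})

test_that("fusion is the convex combination with the documented conventions", {
  mk <- function(C, H, B) new("FeatureMaps", contrast = C, entropy = H,
                              threshold = 0, brightMask = B,
                              window = 5, levels = 256, eps = 2^-52)
  z <- matrix(0, 4, 4)
  # null evidence: F identically zero, mask empty
  cm <- fuseFeatures(mk(z, z, matrix(0L, 4, 4)))
  expect_true(all(combinedScore(cm) == 0))
  expect_equal(sum(combinedMask(cm)), 0)
  # weights (1,0,0): F equals the normalized contrast exactly
  set.seed(25)
  C <- matrix(runif(16), 4, 4); H <- matrix(runif(16), 4, 4)
  B <- matrix(rbinom(16, 1, 0.3), 4, 4)
  cm <- fuseFeatures(mk(C, H, B), weights = c(1, 0, 0))
  expect_equal(combinedScore(cm), (C - min(C)) / diff(range(C)))
  # a pixel maximal in all three maps scores exactly one
  C2 <- C; H2 <- H; B2 <- B
  C2[2, 2] <- max(C) + 1; H2[2, 2] <- max(H) + 1; B2[2, 2] <- 1L
  expect_equal(combinedScore(fuseFeatures(mk(C2, H2, B2)))[2, 2], 1)
  expect_error(fuseFeatures(mk(C, H, B), weights = c(-1, 1, 1)), "weights")
  expect_error(fuseFeatures(mk(C, H, B), weights = c(0, 0, 0)), "weights")
})

test_that("fusion is monotone in each descriptor at a fixed pixel", {
  set.seed(26)
  for (i in 1:20) {
    C <- matrix(runif(64), 8, 8); H <- matrix(runif(64), 8, 8)
    B <- matrix(rbinom(64, 1, 0.3), 8, 8)
    mk <- function(C, H, B) new("FeatureMaps", contrast = C, entropy = H,
                                threshold = 0, brightMask = B,
                                window = 5, levels = 256, eps = 2^-52)
    F0 <- combinedScore(fuseFeatures(mk(C, H, B)))
    # bump a non-maximal pixel of one map; F there must not decrease
    px <- which(C < max(C) - 0.1)[1]
    C2 <- C; C2[px] <- C2[px] + 0.05
    F1 <- combinedScore(fuseFeatures(mk(C2, H, B)))
    expect_gte(F1[px], F0[px] - 1e-12)
    B2 <- B; px2 <- which(B == 0L)[1]; B2[px2] <- 1L
    F2 <- combinedScore(fuseFeatures(mk(C, H, B2)))
    expect_gte(F2[px2], F0[px2] - 1e-12)
  }
})

test_that("minimum intensity projection has its universal properties", {
  set.seed(27)
  frames <- lapply(1:4, function(i) matrix(sample(0:255, 64, TRUE), 8, 8))
  s <- DSASequence(frames)
  m <- minIntensityProjection(s)
  for (i in 1:4) expect_true(all(m <= frames[[i]]))
  # explicit minimum
  expect_equal(m[1, 1], min(vapply(frames, function(f) f[1, 1], numeric(1))))
  # single-frame identity and idempotence
  s1 <- DSASequence(frames[1])
  expect_identical(minIntensityProjection(s1), frames[[1]] + 0)
  expect_identical(minIntensityProjection(DSASequence(list(m))), m)
  # commutes with frame permutation
  sp <- DSASequence(frames[c(3, 1, 4, 2)])
  expect_identical(minIntensityProjection(sp), m)
})

test_that("model input collapses correctly for one frame and stays in [0,1]", {
  set.seed(28)
  fr <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  s <- DSASequence(list(fr), polarity = "vessel_dark")
  mi <- buildModelInput(s)
  # single frame: MinIP is that frame, so the minip channel is its F and
  # the sum channel is the min-max renormalization of the same F
  fB <- normalizeFrame(255 - fr)
  F1 <- combinedScore(fuseFeatures(computeFeatureMaps(fB)))
  expect_equal(mi@minip, F1)
  expect_equal(mi@sum, (F1 - min(F1)) / diff(range(F1)))
  # bounds on a multi-frame stack
  s3 <- DSASequence(lapply(1:3, function(i)
    matrix(sample(0:255, 32 * 32, TRUE), 32, 32)), polarity = "vessel_dark")
  mi3 <- buildModelInput(s3)
  expect_true(all(mi3@minip >= 0 & mi3@minip <= 1))
  expect_true(all(mi3@sum >= 0 & mi3@sum <= 1))
})

test_that("per-frame score sums are monotone in how often a pixel is lit", {
  # a pixel bright in k of n frames accumulates at least the score of a
  # pixel bright once (checked on the unnormalized sum via two pixels)
  base <- matrix(200, 16, 16)
  fr <- function(px) { f <- base; f[px] <- 10; f }  # dark vessel pixel
  frames <- list(fr(c(4)), fr(c(4)), fr(c(4)), fr(c(200)))
  s <- DSASequence(frames, polarity = "vessel_dark")
  pp <- preprocessSequence(s)
  tot <- Reduce(`+`, lapply(pp$combined, combinedScore))
  expect_gte(tot[4], tot[200])
})
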