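test_that("point spread functions are normalized and match their contracts", {
  specs <- list(
    blurSpec("motion", length = 7),
    blurSpec("motion", length = 5, angle = 30),
    blurSpec("gaussian", hsize = 7, sigma = 2),
    blurSpec("disk", radius = 5),
    blurSpec("average", hsize = 13),
    blurSpec("moffat", hsize = 7, s = 1, beta = 5),
    blurSpec("identity"))
  for (sp in specs) {
    k <- psfKernel(makePsf(sp))
    expect_true(all(k >= 0), info = sp@family)
    expect_equal(sum(k), 1, tolerance = 1e-12, info = sp@family)
  }
  ## degenerate line: a unit motion length is the identity, at any angle
  for (ang in c(0, 17, 45, 90))
    expect_equal(psfKernel(makePsf("motion", length = 1, angle = ang)),
                 matrix(1, 1, 1))
  ## rotation symmetry: vertical line is the transpose of the horizontal
  expect_equal(psfKernel(makePsf("motion", length = 5, angle = 90)),
               t(psfKernel(makePsf("motion", length = 5, angle = 0))))
  ## a 7-pixel horizontal line is uniform
  expect_equal(psfKernel(makePsf("motion", length = 7)),
               matrix(1 / 7, 1, 7))
  ## flat-sigma limit of the truncated Gaussian: all weights -> 1/hsize^2
  k <- psfKernel(makePsf("gaussian", hsize = 3, sigma = 1e6))
  expect_equal(k, matrix(1 / 9, 3, 3), tolerance = 1e-10)
  expect_error(blurSpec("gaussian", hsize = -3, sigma = 1), "positive")
  expect_error(blurSpec("motion"), "length")
  expect_error(blurSpec("vortex"), "unknown blur family")
})

test_that("periodic blurring is linear, mean-preserving and matches direct convolution", {
  psf <- makePsf("gaussian", hsize = 3, sigma = 1)
  ## delta image replicates the kernel around the delta
  delta <- matrix(0, 8, 8); delta[4, 5] <- 1
  out <- applyBlur(delta, psf)
  expect_equal(out[3:5, 4:6], psfKernel(psf), tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  ## constant in, constant out (kernel sums to one)
  expect_equal(applyBlur(matrix(3.7, 12, 12), psf), matrix(3.7, 12, 12),
               tolerance = 1e-12)
  ## brute-force spatial convolution oracle
  set.seed(11)
  u <- randImage(8)
  expect_equal(applyBlur(u, psf), directConv(u, psfKernel(psf)),
               tolerance = 1e-12)
  km <- psfKernel(makePsf("motion", length = 5, angle = 30))
  expect_equal(applyBlur(u, makePsf("motion", length = 5, angle = 30)),
               directConv(u, km), tolerance = 1e-12)
  ## linearity on random pairs
  for (rep in 1:5) {
    a <- stats::rnorm(1); b <- stats::rnorm(1)
    u1 <- randImage(16); u2 <- randImage(16)
    expect_equal(applyBlur(a * u1 + b * u2, psf),
                 a * applyBlur(u1, psf) + b * applyBlur(u2, psf),
                 tolerance = 1e-10)
  }
  expect_error(applyBlur(matrix(1, 4, 4), makePsf("average", hsize = 9)),
               "larger than the image")
})

test_that("noise fields have unit mean and the advertised variance", {
  n <- 1000L  # 10^6 samples
  eta <- sampleNoise(c(n, n), noiseSpec("gamma", L = 10, seed = 101))
  ## Gamma(L, 1/L): mean 1 (se sqrt(1/L/n^2)), variance 1/L
  seMean <- sqrt(0.1 / n^2)
  expect_lt(abs(mean(eta) - 1), 3 * seMean)
  ## se of the sample variance ~ sqrt((kurtosis-1)/N) * var; Gamma excess
  ## kurtosis 6/L
  seVar <- 0.1 * sqrt((2 + 6 / 10) / n^2)
  expect_lt(abs(stats::var(as.numeric(eta)) - 0.1), 3 * seVar)
  ## Rayleigh rescaled to mean one
  etaR <- sampleNoise(c(n, n), noiseSpec("rayleigh", seed = 102))
  vR <- 4 / pi - 1
  expect_lt(abs(mean(etaR) - 1), 3 * sqrt(vR / n^2))
  ## vanishing-variance Gaussian collapses to the unit field
  etaG <- sampleNoise(c(32, 32), noiseSpec("gaussian", sigma2 = 1e-16,
                                           seed = 103))
  expect_equal(etaG, matrix(1, 32, 32), tolerance = 1e-6)
  ## speckle variance 0.1 maps onto L = 10 looks
  e1 <- sampleNoise(c(16, 16), noiseSpec("speckle_variance", sigma2 = 0.1,
                                         seed = 104))
  e2 <- sampleNoise(c(16, 16), noiseSpec("gamma", L = 10, seed = 104))
  expect_identical(e1, e2)
  ## reproducibility is bit-exact under a fixed seed
  expect_identical(sampleNoise(c(64, 64), noiseSpec("gamma", L = 6, seed = 9)),
                   sampleNoise(c(64, 64), noiseSpec("gamma", L = 6, seed = 9)))
  expect_error(sampleNoise(c(8, 8), noiseSpec("gamma", L = 10)), "seed")
  expect_error(noiseSpec("gamma", L = 0.5), "L >= 1")
  expect_error(noiseSpec("gaussian", sigma2 = -1), "sigma2")
})

test_that("degradation composes blur and pixelwise noise with a positivity floor", {
  u <- makeTestImage("phantom", n = 32)
  psf <- makePsf("gaussian", hsize = 5, sigma = 1.5)
  ns <- noiseSpec("gamma", L = 10, seed = 5)
  d <- degradeImage(u, psf, ns)
  ## composite equals blur-then-multiply, recomputed term by term
  expect_equal(pixels(d$image),
               pmax(pixels(applyBlur(u, psf)) * d$noise, epsPosOf(u)),
               tolerance = 1e-12)
  ## near-unit noise leaves f = Hu
  d0 <- degradeImage(u, psf, noiseSpec("gaussian", sigma2 = 1e-18, seed = 1))
  expect_equal(pixels(d0$image), pixels(applyBlur(u, psf)), tolerance = 1e-6)
  ## identity psf leaves f = u * eta
  d1 <- degradeImage(u, makePsf("identity"), ns)
  expect_equal(pixels(d1$image), pmax(pixels(u) * d1$noise, epsPosOf(u)),
               tolerance = 1e-12)
  ## bit-reproducible under a fixed seed
  d2 <- degradeImage(u, psf, ns)
  expect_identical(pixels(d$image), pixels(d2$image))
})

test_that("cross-channel blur follows the nine-kernel recipe", {
  ccb <- makeCrossChannelBlur(crossChannelWeights(), seed = 3)
  expect_s4_class(ccb, "CrossChannelBlur")
  ## same seed, same assignment
  ccb2 <- makeCrossChannelBlur(crossChannelWeights(), seed = 3)
  expect_identical(lapply(ccb@kernels, psfKernel),
                   lapply(ccb2@kernels, psfKernel))
  ## identity weights: off-diagonal blocks are zero operators
  cid <- makeCrossChannelBlur(diag(3), seed = 3)
  u3 <- imageGrid(array(stats::runif(48 * 48 * 3, 1, 255), c(48, 48, 3)))
  out <- applyBlur(u3, cid)
  for (k in 1:3)
    expect_equal(channelMatrixOf(out, k),
                 applyBlur(channelMatrixOf(u3, k), cid@kernels[[(k - 1) * 3 + k]]),
                 tolerance = 1e-12)
  ## channelwise-constant image: channel k becomes c * sum_j w_kj
  W <- crossChannelWeights()
  cc <- imageGrid(array(100, c(48, 48, 3)))
  outc <- applyBlur(cc, makeCrossChannelBlur(W, seed = 7))
  for (k in 1:3)
    expect_equal(channelMatrixOf(outc, k),
                 matrix(100 * sum(W[k, ]), 48, 48), tolerance = 1e-10)
  expect_error(makeCrossChannelBlur(diag(2), seed = 1), "3 x 3")
  expect_error(applyBlur(imageGrid(matrix(1, 48, 48)), cid), "channels")
})

test_that("synthetic test images match their analytic definitions", {
  ## constant
  expect_true(all(pixels(makeTestImage("constant", n = 16)) == 255 / 2))
  ## phantom range and ellipse-membership oracle
  ph <- makeTestImage("phantom", n = 64)
  fl <- epsPosOf(ph)
  expect_true(all(pixels(ph) >= fl & pixels(ph) <= 255))
  expect_equal(pixels(ph), fl + (255 - fl) * phantomOracle(64),
               tolerance = 1e-12)
  ## affine ramp increments
  ar <- pixels(makeTestImage("affine_ramp", n = 32, a = 2, b = 3, c = 5))
  expect_equal(ar[10, 7] , 2 * 9 + 3 * 6 + 5)
  expect_equal(unique(diff(ar[, 4])), 2)
  ## piecewise-constant staircase stays in range with 16 levels
  pc <- pixels(makeTestImage("piecewise_constant", n = 32))
  expect_equal(length(unique(as.numeric(pc))), 16L)
  expect_error(makeTestImage("phantom", n = 8), ">= 16")
})
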