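## small helper: a zeroed ADMM state for an m x m image
zeroState <- function(u) {
  m <- dim(u)
  zero <- matrix(0, m[1], m[2])
  sys <- if (min(m) >= 32) buildShearletSystem(m[1], m[2], 2L)
         else shearTGV:::trivialShearletSystem(m[1], m[2])
  nb <- length(filters(sys))
  new("ADMMState", u = u, p = vectorField(zero, zero),
      x = rep(list(zero), nb), xd = rep(list(zero), nb),
      y = vectorField(zero, zero), yd = vectorField(zero, zero),
      z = symTensorField(zero, zero, zero),
      zd = symTensorField(zero, zero, zero),
      t = u, td = zero, iter = 0L,
      history = data.frame())
}

test_that("the energy matches a term-by-term oracle and its closed-form values", {
  set.seed(61)
  ## u = f = 1 with negligible regularizers: log 1 + 1 + 0 per pixel
  one <- matrix(1, 16, 16)
  cfg0 <- solverConfig(lambda = 1e-12, gamma0 = 1e-12, gamma1 = 1e-12,
                       alpha = 3)
  expect_equal(m4Energy(one, NULL, one, NULL, cfg0), 256, tolerance = 1e-9)
  ## u = 2f, alpha = 1: sum log(2f) + n/2 + n
  f <- matrix(stats::runif(256, 0.5, 2), 16, 16)
  cfg1 <- suppressWarnings(
    solverConfig(lambda = 1e-12, gamma0 = 1e-12, gamma1 = 1e-12, alpha = 1))
  expect_equal(m4Energy(2 * f, NULL, f, NULL, cfg1),
               sum(log(2 * f)) + 128 + 256, tolerance = 1e-9)
  ## full energy against independently recomputed terms on a random instance
  u <- matrix(stats::runif(256, 0.5, 3), 16, 16)
  p <- randVF(16)
  cfg <- solverConfig(lambda = 0.8, alpha = 3, gamma1 = 0.7, gamma0 = 1.1,
                      penalizeLowpass = TRUE)
  sys <- shearTGV:::trivialShearletSystem(16L, 16L)
  co <- sum(abs(u))  # trivial system: the single band is u itself
  g <- gradOracle(u)
  e <- symGradOracle(p@v1, p@v2)
  expected <- sum(log(u)) + sum(f / u) + 3 * sum((u / f - 1)^2) +
    0.8 * co +
    0.7 * sum(sqrt((g$v1 - p@v1)^2 + (g$v2 - p@v2)^2)) +
    1.1 * sum(sqrt(e$w11^2 + 2 * e$w12^2 + e$w22^2))
  expect_equal(m4Energy(u, p, f, NULL, cfg, system = sys), expected,
               tolerance = 1e-10)
  expect_error(m4Energy(u - 10, NULL, f, NULL, cfg, system = sys),
               "strictly positive")
})

test_that("the (u,p) subproblem is stationary at consistent anchors", {
  ## all anchors consistent with u = f, H = I: the subproblem returns u = f
  set.seed(62)
  f <- matrix(stats::runif(64^2, 50, 200), 64, 64)
  cfg <- solverConfig(lambda = 1e-12, nScales = 2, maxIter = 10)
  sys <- buildShearletSystem(64, 64, 2)
  st <- zeroState(f)
  st@x <- bands(shearletForward(f, sys))  # x_j = SH_j(f)
  g <- imageGradient(f)
  st@y <- g                                # y = grad f - p with p = 0
  st@t <- f
  out <- solveUpSubproblem(st, f, NULL, cfg, system = sys, sweeps = 3)
  expect_lt(max(abs(out@u - f)), 1e-8 * max(f))
})

test_that("with the fidelity disabled the subproblem solves the quadratic normal equations", {
  set.seed(63)
  n <- 8L
  sys <- shearTGV:::trivialShearletSystem(n, n)
  cfg <- solverConfig(lambda = 0.5, mu1 = 3, mu2 = 2, mu3 = 1.5, nScales = 1)
  st <- zeroState(matrix(stats::runif(n * n), n, n))
  st@x <- list(randImage(n))
  st@y <- randVF(n); st@yd <- randVF(n)
  st@z <- randTF(n); st@zd <- randTF(n)
  out <- solveUpSubproblem(st, NULL, NULL, cfg, system = sys, sweeps = 1,
                           epsPosVal = -Inf)
  ## conjugate-gradient oracle on the stacked normal equations
  ## variables v = (u, p1, p2); operator A v and rhs b assembled via the
  ## package's forward operators only (adjoints realized by inner products
  ## is overkill: use the negative-divergence adjoint identities directly)
  cx <- st@x[[1]] - st@xd[[1]]
  cy <- vectorField(st@y@v1 - st@yd@v1, st@y@v2 - st@yd@v2)
  cz <- symTensorField(st@z@w11 - st@zd@w11, st@z@w12 - st@zd@w12,
                       st@z@w22 - st@zd@w22)
  Aop <- function(v) {
    u <- v[[1]]; p <- vectorField(v[[2]], v[[3]])
    gu <- imageGradient(u)
    r1 <- cfg@mu1 * u -
      cfg@mu2 * divergence1(vectorField(gu@v1 - p@v1, gu@v2 - p@v2))
    ep <- symGradient(p)
    d2 <- divergence2(ep)
    r2 <- -cfg@mu2 * (gu@v1 - p@v1) - cfg@mu3 * d2@v1
    r3 <- -cfg@mu2 * (gu@v2 - p@v2) - cfg@mu3 * d2@v2
    list(r1, r2, r3)
  }
  dcz <- divergence2(cz)
  b <- list(cfg@mu1 * cx - cfg@mu2 * divergence1(cy),
            -cfg@mu2 * cy@v1 - cfg@mu3 * dcz@v1,
            -cfg@mu2 * cy@v2 - cfg@mu3 * dcz@v2)
  ## plain CG on the SPD system
  v <- lapply(1:3, function(i) matrix(0, n, n))
  r <- b; pdir <- r
  rs <- sum(unlist(r)^2)
  for (k in 1:400) {
    Ap <- Aop(pdir)
    alpha <- rs / sum(unlist(pdir) * unlist(Ap))
    v <- mapply(function(a, b) a + alpha * b, v, pdir, SIMPLIFY = FALSE)
    r <- mapply(function(a, b) a - alpha * b, r, Ap, SIMPLIFY = FALSE)
    rs2 <- sum(unlist(r)^2)
    if (sqrt(rs2) < 1e-12) break
    pdir <- mapply(function(a, b) a + (rs2 / rs) * b, r, pdir,
                   SIMPLIFY = FALSE)
    rs <- rs2
  }
  expect_lt(max(abs(out@u - v[[1]])), 1e-6)
  expect_lt(max(abs(out@p@v1 - v[[2]])), 1e-6)
  expect_lt(max(abs(out@p@v2 - v[[3]])), 1e-6)
})

test_that("on a single pixel the subproblem matches a brute-force 1-D minimizer", {
  ## 1x1 image: all difference operators vanish; the subproblem reduces to
  ## min_u phi(u) + mu1/2 (u - cx)^2 with phi the pointwise fidelity
  f <- matrix(2.0, 1, 1)
  cfg <- solverConfig(lambda = 1e-12, mu0 = 4, mu1 = 3, nScales = 1,
                      innerSweeps = 60L)
  sys <- shearTGV:::trivialShearletSystem(1L, 1L)
  st <- zeroState(f)
  st@x <- list(matrix(1.2, 1, 1))
  st@t <- f
  out <- solveUpSubproblem(st, f, NULL, cfg, system = sys,
                           sweeps = 60, epsPosVal = 1e-6)
  obj <- function(uu) log(uu) + 2 / uu + cfg@alpha * (uu / 2 - 1)^2 +
    cfg@mu1 / 2 * (uu - 1.2)^2
  grid <- seq(0.05, 5, by = 1e-5)
  uStar <- grid[which.min(obj(grid))]
  expect_lt(abs(out@u[1, 1] - uStar), 1e-4)
})

test_that("a constant image is an exact fixed point when the low-pass band is unpenalized", {
  f <- makeTestImage("constant", n = 64)
  cfg <- solverConfig(lambda = 3, penalizeLowpass = FALSE, nScales = 2,
                      maxIter = 25, mu1 = 5, mu2 = 5, mu3 = 5)
  res <- admmRestore(f, makePsf("identity"), cfg)
  expect_lt(max(abs(pixels(restoredImage(res)) - pixels(f))), 1e-3 * 255)
})

test_that("restoration is deterministic, improves PSNR and drives the residuals down", {
  u <- makeTestImage("phantom", n = 64)
  d <- degradeImage(u, makePsf("identity"), noiseSpec("gamma", L = 10,
                                                      seed = 7))
  cfg <- solverConfig(lambda = 5, gamma1 = 1, gamma0 = 2, maxIter = 60,
                      nScales = 2, penalizeLowpass = FALSE)
  r1 <- admmRestore(d$image, makePsf("identity"), cfg)
  r2 <- admmRestore(d$image, makePsf("identity"), cfg)
  expect_identical(pixels(restoredImage(r1)), pixels(restoredImage(r2)))
  expect_gt(psnr(restoredImage(r1), u), psnr(d$image, u))
  h <- solverHistory(r1)
  ## primal residuals of all constraint groups fall well below their early
  ## levels (the first row has all-zero splits, so compare to iteration 2)
  expect_lt(h$resX[nrow(h)], 0.2 * h$resX[2])
  expect_lt(h$resY[nrow(h)], 0.2 * h$resY[2])
  expect_lt(h$resZ[nrow(h)], max(0.2 * h$resZ[2], 1e-10))
  ## energy is non-increasing after burn-in, up to small ADMM oscillation
  post <- h$energy[10:nrow(h)]
  expect_true(all(diff(post) <= 1e-4 * abs(post[-length(post)]) + 1e-8))
})

test_that("an invalid configuration is rejected and a weak alpha warns", {
  expect_warning(solverConfig(alpha = 1), "26/9")
  expect_error(solverConfig(lambda = -1), "> 0")
  expect_error(solverConfig(tol = 0), "> 0")
})
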