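test_that("difference operators match componentwise oracles", {
  set.seed(31)
  u <- randImage(5)
  g <- imageGradient(u)
  go <- gradOracle(u)
  expect_equal(g@v1, go$v1, tolerance = 1e-12)
  expect_equal(g@v2, go$v2, tolerance = 1e-12)
  v <- randVF(5)
  e <- symGradient(v)
  eo <- symGradOracle(v@v1, v@v2)
  expect_equal(e@w11, eo$w11, tolerance = 1e-12)
  expect_equal(e@w12, eo$w12, tolerance = 1e-12)
  expect_equal(e@w22, eo$w22, tolerance = 1e-12)
  ## constants are annihilated
  gz <- imageGradient(matrix(7, 9, 9))
  expect_true(all(gz@v1 == 0) && all(gz@v2 == 0))
  ez <- symGradient(vectorField(matrix(2, 9, 9), matrix(-3, 9, 9)))
  expect_true(all(ez@w11 == 0) && all(ez@w12 == 0) && all(ez@w22 == 0))
  ## zero fields map to zero under the divergences
  z <- vectorField(matrix(0, 6, 6), matrix(0, 6, 6))
  expect_true(all(divergence1(z) == 0))
  d2 <- divergence2(symTensorField(matrix(0, 6, 6), matrix(0, 6, 6),
                                   matrix(0, 6, 6)))
  expect_true(all(d2@v1 == 0) && all(d2@v2 == 0))
})

test_that("interior behavior on affine images: gradient constant, second differences vanish", {
  u <- pixels(makeTestImage("affine_ramp", n = 16, a = 2, b = 3, c = 1))
  g <- imageGradient(u)
  inner <- 2:14  # away from the periodic wrap seam
  expect_true(all(abs(g@v1[inner, inner] - 2) < 1e-12))
  expect_true(all(abs(g@v2[inner, inner] - 3) < 1e-12))
  e <- symGradient(g)
  inner2 <- 3:14
  expect_true(all(abs(e@w11[inner2, inner2]) < 1e-12))
  expect_true(all(abs(e@w12[inner2, inner2]) < 1e-12))
  expect_true(all(abs(e@w22[inner2, inner2]) < 1e-12))
})

test_that("adjoint identities hold to 1e-10 across random instances and sizes", {
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(8:64, 1)
    u <- randImage(n); v <- randVF(n); w <- randTF(n)
    g <- imageGradient(u)
    expect_equal(innerVF(g, v), -sum(u * divergence1(v)), tolerance = 1e-10)
    e <- symGradient(v)
    expect_equal(innerTF(e, w), -innerVF(v, divergence2(w)),
                 tolerance = 1e-10)
  }
})

test_that("div1 of grad is the 5-point Laplacian", {
  set.seed(33)
  u <- randImage(12)
  lap <- divergence1(imageGradient(u))
  lap2 <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    lap2[i, j] <- u[i %% 12 + 1, j] + u[(i - 2) %% 12 + 1, j] +
      u[i, j %% 12 + 1] + u[i, (j - 2) %% 12 + 1] - 4 * u[i, j]
  }
  expect_equal(lap, lap2, tolerance = 1e-12)
})

test_that("the TGV2 functional vanishes on constants, is bounded by feasibility and convex-consistent", {
  expect_equal(tgv2Value(matrix(6, 32, 32), 2, 1, nIter = 50), 0)
  ## v = 0 feasibility bound on random images
  set.seed(34)
  for (rep in 1:3) {
    u <- randImage(32)
    g <- imageGradient(u)
    bound <- 1.3 * sum(sqrt(g@v1^2 + g@v2^2))
    expect_lte(tgv2Value(u, 2, 1.3, nIter = 60), bound + 1e-9)
  }
  ## on an affine ramp the optimal v = grad u zeroes the first-order term and
  ## the second-order term away from the periodic seam: the minimized value
  ## must undercut both single-term feasible points by a wide margin
  u <- pixels(makeTestImage("affine_ramp", n = 32, a = 4, b = 2, c = 1))
  g <- imageGradient(u)
  atV0 <- 1 * sum(sqrt(g@v1^2 + g@v2^2))
  e <- symGradient(g)
  atVg <- 2 * sum(sqrt(e@w11^2 + 2 * e@w12^2 + e@w22^2))
  val <- tgv2Value(u, gamma0 = 2, gamma1 = 1, nIter = 300)
  expect_lte(val, min(atV0, atVg) + 1e-9)
  ## positive 1-homogeneity of the seminorm (within solver slack)
  expect_equal(tgv2Value(2 * u, gamma0 = 2, gamma1 = 1, nIter = 300),
               2 * val, tolerance = 0.05)
  ## convexity consistency on random pairs
  set.seed(35)
  for (rep in 1:3) {
    u1 <- randImage(24); u2 <- randImage(24)
    vmid <- tgv2Value((u1 + u2) / 2, 2, 1, nIter = 80)
    expect_lte(vmid, 0.5 * (tgv2Value(u1, 2, 1, nIter = 80) +
                              tgv2Value(u2, 2, 1, nIter = 80)) + 1e-6)
  }
  expect_error(tgv2Value(matrix(1, 16, 16), -1, 1), "> 0")
})
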