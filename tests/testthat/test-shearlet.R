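test_that("the filter bank is a Parseval frame with low/band-pass structure", {
  for (dims in list(c(64L, 64L, 2L), c(64L, 96L, 2L), c(45L, 33L, 1L),
                    c(128L, 128L, 3L))) {
    sys <- buildShearletSystem(dims[1], dims[2], dims[3])
    s <- Reduce(`+`, lapply(filters(sys), function(h) h^2))
    expect_lt(max(abs(s - 1)), 1e-10)
    ## DC: the low-pass responds fully, every directional band vanishes
    expect_equal(filters(sys)[[1]][1, 1], 1)
    for (j in seq_along(filters(sys))[-1])
      expect_equal(filters(sys)[[j]][1, 1], 0)
  }
  ## band count grows strictly with the scale count
  n1 <- length(filters(buildShearletSystem(64, 64, 1)))
  n2 <- length(filters(buildShearletSystem(64, 64, 2)))
  expect_gt(n2, n1)
  expect_error(buildShearletSystem(16, 64, 1), "32")
  expect_error(buildShearletSystem(32, 32, 4), "too small")
})

test_that("forward transform is linear, real and shape-checked", {
  sys <- buildShearletSystem(64, 64, 2)
  zero <- shearletForward(matrix(0, 64, 64), sys)
  for (b in bands(zero)) expect_true(all(b == 0))
  set.seed(21)
  u1 <- randImage(64); u2 <- randImage(64)
  a <- 0.7; b <- -1.3
  c1 <- bands(shearletForward(u1, sys))
  c2 <- bands(shearletForward(u2, sys))
  cc <- bands(shearletForward(a * u1 + b * u2, sys))
  for (j in seq_along(cc))
    expect_equal(cc[[j]], a * c1[[j]] + b * c2[[j]], tolerance = 1e-10)
  ## constant image: only the low-pass band is nonzero
  ck <- bands(shearletForward(matrix(4.2, 64, 64), sys))
  expect_equal(ck[[1]], matrix(4.2, 64, 64), tolerance = 1e-10)
  for (j in seq_along(ck)[-1])
    expect_lt(max(abs(ck[[j]])), 1e-10)
  expect_error(shearletForward(matrix(0, 32, 32), sys), "shape")
})

test_that("the adjoint inverts the forward transform and satisfies the adjoint identity", {
  set.seed(22)
  for (dims in list(c(64L, 64L, 2L), c(45L, 33L, 1L))) {
    sys <- buildShearletSystem(dims[1], dims[2], dims[3])
    u <- randImage(dims[1], dims[2])
    co <- shearletForward(u, sys)
    ## Parseval: adjoint o forward = identity
    expect_lt(max(abs(shearletAdjoint(co, sys) - u)), 1e-10)
    ## energy split
    expect_equal(sum(vapply(bands(co), function(b) sum(b^2), numeric(1))),
                 sum(u^2), tolerance = 1e-8)
    ## <forward(u), c> = <u, adjoint(c)>
    cl <- lapply(filters(sys), function(h) randImage(dims[1], dims[2]))
    lhs <- sum(mapply(function(a, b) sum(a * b), bands(co), cl))
    rhs <- sum(u * shearletAdjoint(
      new("ShearletCoeffs", bands = cl, shape = sys@shape), sys))
    expect_equal(lhs, rhs, tolerance = 1e-8)
    ## zero coefficients map to the zero image
    z <- lapply(filters(sys), function(h) matrix(0, dims[1], dims[2]))
    expect_true(all(shearletAdjoint(
      new("ShearletCoeffs", bands = z, shape = sys@shape), sys) == 0))
  }
  sys <- buildShearletSystem(64, 64, 2)
  bad <- new("ShearletCoeffs",
             bands = rep(list(matrix(0, 64, 64)), 3), shape = c(64L, 64L))
  expect_error(shearletAdjoint(bad, sys), "bands")
})
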