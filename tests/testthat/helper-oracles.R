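## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's FFT / vectorized code paths.

## O(n^2 k^2) periodic spatial convolution with the kernel anchored at its
## center index
directConv <- function(u, kernel) {
  m1 <- nrow(u); m2 <- ncol(u)
  k1 <- nrow(kernel); k2 <- ncol(kernel)
  c1 <- (k1 + 1) %/% 2; c2 <- (k2 + 1) %/% 2
  out <- matrix(0, m1, m2)
  for (i in seq_len(m1)) for (j in seq_len(m2)) {
    acc <- 0
    for (a in seq_len(k1)) for (b in seq_len(k2)) {
      ii <- ((i - (a - c1)) - 1) %% m1 + 1
      jj <- ((j - (b - c2)) - 1) %% m2 + 1
      acc <- acc + kernel[a, b] * u[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

## per-pixel ellipse-membership evaluation of the modified Shepp-Logan
## phantom on the MATLAB grid convention (plain double loop)
phantomOracle <- function(n) {
  E <- matrix(c(
     1.0, 0.69,   0.92,   0,     0,      0,
    -0.8, 0.6624, 0.8740, 0,    -0.0184, 0,
    -0.2, 0.1100, 0.3100, 0.22,  0,    -18,
    -0.2, 0.1600, 0.4100,-0.22,  0,     18,
     0.1, 0.2100, 0.2500, 0,     0.35,   0,
     0.1, 0.0460, 0.0460, 0,     0.1,    0,
     0.1, 0.0460, 0.0460, 0,    -0.1,    0,
     0.1, 0.0460, 0.0230,-0.08, -0.605,  0,
     0.1, 0.0230, 0.0230, 0,    -0.606,  0,
     0.1, 0.0230, 0.0460, 0.06, -0.605,  0), ncol = 6, byrow = TRUE)
  g <- seq(-1, 1, length.out = n)
  v <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- g[j]; y <- g[n - i + 1]
    acc <- 0
    for (e in seq_len(nrow(E))) {
      phi <- E[e, 6] * pi / 180
      xr <- (x - E[e, 4]) * cos(phi) + (y - E[e, 5]) * sin(phi)
      yr <- -(x - E[e, 4]) * sin(phi) + (y - E[e, 5]) * cos(phi)
      if ((xr / E[e, 2])^2 + (yr / E[e, 3])^2 <= 1) acc <- acc + E[e, 1]
    }
    v[i, j] <- min(max(acc, 0), 1)
  }
  v
}

## brute-force proximal oracles via 1-D numerical minimization
proxAbsOracle <- function(v, sigma) {
  stats::optimize(function(x) sigma * abs(x) + 0.5 * (x - v)^2,
                  interval = c(-3, 3), tol = 1e-9)$minimum
}

## prox of mu * l2-norm of a 2-vector: minimize over the radius along a's
## direction (the minimizer is radial); covers the a = 0 clamp
proxVecOracle <- function(a, mu) {
  na <- sqrt(sum(a^2))
  if (na == 0) return(c(0, 0))
  r <- stats::optimize(function(r) mu * abs(r) + 0.5 * (r - na)^2,
                       interval = c(-na - 1, na + 1), tol = 1e-9)$minimum
  a / na * r
}

## componentwise periodic difference oracles (index arithmetic, no shifts)
gradOracle <- function(u) {
  m1 <- nrow(u); m2 <- ncol(u)
  v1 <- v2 <- matrix(0, m1, m2)
  for (i in seq_len(m1)) for (j in seq_len(m2)) {
    v1[i, j] <- u[i %% m1 + 1, j] - u[i, j]
    v2[i, j] <- u[i, j %% m2 + 1] - u[i, j]
  }
  list(v1 = v1, v2 = v2)
}

symGradOracle <- function(v1, v2) {
  m1 <- nrow(v1); m2 <- ncol(v1)
  w11 <- w12 <- w22 <- matrix(0, m1, m2)
  for (i in seq_len(m1)) for (j in seq_len(m2)) {
    dxv1 <- v1[i, j] - v1[(i - 2) %% m1 + 1, j]
    dyv1 <- v1[i, j] - v1[i, (j - 2) %% m2 + 1]
    dxv2 <- v2[i, j] - v2[(i - 2) %% m1 + 1, j]
    dyv2 <- v2[i, j] - v2[i, (j - 2) %% m2 + 1]
    w11[i, j] <- dxv1
    w22[i, j] <- dyv2
    w12[i, j] <- 0.5 * (dyv1 + dxv2)
  }
  list(w11 = w11, w12 = w12, w22 = w22)
}

## shorthands for package internals used only to state expectations
epsPosOf <- function(img) shearTGV:::epsPos(nMax(img))
channelMatrixOf <- function(img, k) shearTGV:::channelMatrix(img, k)

## random test fixtures
randImage <- function(m1, m2 = m1) matrix(stats::rnorm(m1 * m2), m1, m2)
randVF <- function(m1, m2 = m1) vectorField(randImage(m1, m2), randImage(m1, m2))
randTF <- function(m1, m2 = m1)
  symTensorField(randImage(m1, m2), randImage(m1, m2), randImage(m1, m2))

innerVF <- function(a, b) sum(a@v1 * b@v1 + a@v2 * b@v2)
innerTF <- function(a, b) sum(a@w11 * b@w11 + 2 * a@w12 * b@w12 + a@w22 * b@w22)
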