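## Internal numerical helpers: FFT wrappers, circular shifts, kernel-to-OTF
## embedding. All solver linear algebra funnels through these.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## inverse FFT of a spectrum known to represent a real field; asserts the
## imaginary residue is negligible before discarding it
ifft2Real <- function(x, tol = 1e-8) {
  y <- ifft2(x)
  m <- max(abs(Im(y)))
  s <- max(abs(Re(y)), 1)
  if (m > tol * s)
    stop("imaginary residue ", format(m), " exceeds tolerance; ",
         "spectrum is not conjugate-symmetric")
  Re(y)
}

## circularly shift a matrix by (di, dj); positive shifts move content down/right
circShift <- function(x, di, dj) {
  m <- nrow(x); n <- ncol(x)
  di <- ((di %% m) + m) %% m
  dj <- ((dj %% n) + n) %% n
  if (di > 0) x <- x[c((m - di + 1L):m, 1L:(m - di)), , drop = FALSE]
  if (dj > 0) x <- x[, c((n - dj + 1L):n, 1L:(n - dj)), drop = FALSE]
  x
}

## embed a (small) kernel into an m1 x m2 array with its anchor at (1,1),
## then FFT: the optical transfer function of periodic convolution
psf2otf <- function(kernel, m1, m2) {
  k1 <- nrow(kernel); k2 <- ncol(kernel)
  if (k1 > m1 || k2 > m2)
    stop("kernel (", k1, "x", k2, ") is larger than the image (",
         m1, "x", m2, ")")
  big <- matrix(0, m1, m2)
  big[seq_len(k1), seq_len(k2)] <- kernel
  ## anchor = center index (ceiling of half size), moved to (1,1)
  c1 <- (k1 + 1L) %/% 2L
  c2 <- (k2 + 1L) %/% 2L
  fft2(circShift(big, -(c1 - 1L), -(c2 - 1L)))
}

## signed integer frequencies 0, 1, ..., -1 matching R's fft layout
fftFreq <- function(m) {
  k <- seq_len(m) - 1L
  ifelse(k > m / 2, k - m, k)
}

## Fourier symbols of the periodic forward/backward difference operators,
## as m1 x m2 complex matrices (x = first index / rows, y = second / cols)
diffSymbols <- function(m1, m2) {
  t1 <- 2 * pi * fftFreq(m1) / m1
  t2 <- 2 * pi * fftFreq(m2) / m2
  ex <- exp(1i * t1); ey <- exp(1i * t2)
  dxp <- matrix(ex - 1, m1, m2)
  dyp <- matrix(ey - 1, m1, m2, byrow = TRUE)
  dxm <- matrix(1 - Conj(ex), m1, m2)
  dym <- matrix(1 - Conj(ey), m1, m2, byrow = TRUE)
  list(dxp = dxp, dyp = dyp, dxm = dxm, dym = dym,
       lap = Mod(dxp)^2 + Mod(dyp)^2)
}

## positivity floor for intensities on a [0, nMax] scale
epsPos <- function(nMax = 255, rel = 1e-3) rel * nMax

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## coerce ImageGrid or bare matrix/array to the pixel array
asPixels <- function(x) {
  if (is(x, "ImageGrid")) pixels(x) else x
}
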