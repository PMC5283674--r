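#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Band-limited shearlet-type frame, built entirely in the Fourier domain from
## Meyer windows: a telescoping radial partition (squares summing to one) and,
## per scale, an angular partition of the half-circle whose number of
## directions doubles per scale (the discrete analogue of parabolic scaling).
## Every filter is real and symmetric under omega -> -omega, so real images
## have real coefficients, and the squared filter responses sum to one at
## every frequency: the frame operator is exactly the identity.
## ---------------------------------------------------------------------------

## Meyer's C^3 transition polynomial: 0 -> 1 on [0, 1]
meyerNu <- function(x) {
  x <- clamp(x, 0, 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

## smooth step: 0 below a, 1 above b, sin(pi/2 nu) ramp between
meyerStep <- function(r, a, b) sin(pi / 2 * meyerNu((r - a) / (b - a)))

## squared-complementary angular bump: v(0) = 1, support (-1, 1),
## v(x)^2 + v(1 - x)^2 = 1
meyerBump <- function(x) cos(pi / 2 * meyerNu(abs(x)))

## cache of built systems, keyed by shape and scale count
.shearletCache <- new.env(parent = emptyenv())

#' Build a band-limited shearlet system
#'
#' Constructs the Meyer-window, cone-adapted band-limited filter bank
#' \eqn{\{H_j\}} for an m1 x m2 grid: one low-pass (scaling) filter plus,
#' for scale \eqn{s = 1..n}, \eqn{2^{s+1}} directional filters covering both
#' frequency cones. Radially the scales tile dyadic annuli with breakpoints
#' at \eqn{2^{s-n}} of the Nyquist frequency; the directional windows
#' partition the orientation half-circle. Squares of all responses sum to
#' one at every frequency (a Parseval frame, checked by the class validity),
#' so \code{\link{shearletAdjoint}} is an exact inverse of
#' \code{\link{shearletForward}}. Systems are cached per (shape, scales).
#'
#' @param m1,m2 grid dimensions, both >= 32.
#' @param nScales number of directional scales (>= 1). More scales refine
#'   the low-frequency annuli; the band count is \eqn{1 + \sum_s 2^{s+1}}.
#' @return a \linkS4class{ShearletSystem}.
#' @examples
#' sys <- buildShearletSystem(64, 64, nScales = 2)
#' sys
#' @export
buildShearletSystem <- function(m1, m2, nScales = 4L) {
  m1 <- as.integer(m1); m2 <- as.integer(m2); nScales <- as.integer(nScales)
  if (nScales < 1L) stop("'nScales' must be >= 1")
  if (m1 < 32L || m2 < 32L)
    stop("image must be at least 32 x 32 for a directional system")
  if (min(m1, m2) < 2^(nScales + 2))
    stop("image of size ", m1, " x ", m2, " is too small for ", nScales,
         " scales")
  key <- paste(m1, m2, nScales, sep = "x")
  hit <- get0(key, envir = .shearletCache)
  if (!is.null(hit)) return(hit)

  w1 <- fftFreq(m1) / (m1 / 2)
  w2 <- fftFreq(m2) / (m2 / 2)
  X <- matrix(w1, m1, m2)            # first-axis frequency, Nyquist = 1
  Y <- matrix(w2, m1, m2, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X) %% pi          # orientation on the half-circle

  ## telescoping radial squares: lowpass^2 = 1 - F_1^2,
  ## band_s^2 = F_s^2 - F_{s+1}^2, finest band F_n^2 (covers to the corners)
  rho <- 2^((0:nScales) - nScales)
  Fs <- lapply(seq_len(nScales), function(s)
    meyerStep(r, rho[s], rho[s + 1]))
  Fs[[nScales + 1L]] <- matrix(0, m1, m2)

  filters <- list(sqrt(pmax(1 - Fs[[1L]]^2, 0)))
  for (s in seq_len(nScales)) {
    B2 <- pmax(Fs[[s]]^2 - Fs[[s + 1L]]^2, 0)
    D <- 2L^(s + 1L)                  # directions on the half-circle
    ang <- theta * D / pi
    for (k in 0:(D - 1L)) {
      ## periodic distance to direction center k on the half-circle
      dx <- (ang - k + D / 2) %% D - D / 2
      V <- meyerBump(dx)
      filters[[length(filters) + 1L]] <- sqrt(B2) * V
    }
  }
  ## enforce H(-omega) = H(omega) exactly (real coefficients for real
  ## images): quadratic averaging with the negated-frequency filter keeps
  ## sum_j H_j^2 = 1 intact. Off the self-paired Nyquist lines of an
  ## even-sized grid the filters are already symmetric and are unchanged.
  ni <- c(1L, rev(seq_len(m1)[-1L]))
  nj <- c(1L, rev(seq_len(m2)[-1L]))
  filters <- lapply(filters, function(h) sqrt((h^2 + h[ni, nj]^2) / 2))

  sys <- new("ShearletSystem", filters = filters, nScales = nScales,
             shape = c(m1, m2))
  assign(key, sys, envir = .shearletCache)
  sys
}

#' @rdname accessors
setMethod("filters", "ShearletSystem", function(x) x@filters)

#' @rdname accessors
setMethod("nScales", "ShearletSystem", function(x) x@nScales)

#' @rdname accessors
setMethod("systemShape", "ShearletSystem", function(x) x@shape)

#' @rdname accessors
setMethod("bands", "ShearletCoeffs", function(x) x@bands)

## forward transform of a spectrum already in the Fourier domain
shearletForwardSpec <- function(uhat, system) {
  lapply(system@filters, function(h) ifft2Real(h * uhat))
}

#' @describeIn shearletForward transform of a bare matrix.
setMethod("shearletForward", signature("matrix", "ShearletSystem"),
  function(x, system) {
    if (!all(dim(x) == system@shape))
      stop("image shape ", paste(dim(x), collapse = " x "),
           " does not match the system shape ",
           paste(system@shape, collapse = " x "))
    new("ShearletCoeffs", bands = shearletForwardSpec(fft2(x), system),
        shape = system@shape)
  })

#' @describeIn shearletForward transform of a single-channel image.
setMethod("shearletForward", signature("ImageGrid", "ShearletSystem"),
  function(x, system) {
    if (nChannels(x) != 1L)
      stop("shearletForward transforms one channel at a time")
    shearletForward(channelMatrix(x), system)
  })

#' @describeIn shearletForward adjoint (= inverse, Parseval) transform of a
#'   coefficient stack.
setMethod("shearletAdjoint", signature("ShearletCoeffs", "ShearletSystem"),
  function(x, system) {
    if (length(x@bands) != length(system@filters))
      stop("coefficient stack has ", length(x@bands),
           " bands but the system has ", length(system@filters))
    if (!all(x@shape == system@shape))
      stop("coefficient shape does not match the system shape")
    acc <- matrix(0i, system@shape[1], system@shape[2])
    for (j in seq_along(x@bands))
      acc <- acc + system@filters[[j]] * fft2(x@bands[[j]])
    ifft2Real(acc)
  })

#' @describeIn shearletForward adjoint applied to a plain list of band
#'   matrices (solver-internal fast path).
setMethod("shearletAdjoint", signature("list", "ShearletSystem"),
  function(x, system) {
    acc <- matrix(0i, system@shape[1], system@shape[2])
    for (j in seq_along(x))
      acc <- acc + system@filters[[j]] * fft2(x[[j]])
    ifft2Real(acc)
  })

#' Export shearlet coefficients as a multi-page TIFF
#'
#' Debug helper: writes each band, affinely rescaled to [0, 1], as one page
#' of a 32-bit float TIFF.
#'
#' @param coeffs a \linkS4class{ShearletCoeffs}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCoeffsTiff <- function(coeffs, path) {
  pages <- lapply(coeffs@bands, function(b) {
    r <- range(b)
    if (diff(r) == 0) b * 0 else (b - r[1]) / diff(r)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
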