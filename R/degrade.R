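#' @include ImageGrid-methods.R
NULL

#' Describe a blur family
#'
#' Builds a \linkS4class{BlurSpec} with the parameters the corresponding
#' MATLAB-style generator expects:
#' \describe{
#'   \item{motion}{\code{length} (pixels), \code{angle} (degrees,
#'     anticlockwise); an anti-aliased line segment.}
#'   \item{gaussian}{\code{hsize} (window side), \code{sigma}; truncated
#'     isotropic Gaussian.}
#'   \item{disk}{\code{radius}; pillbox with fractional edge pixels.}
#'   \item{average}{\code{hsize}; uniform window.}
#'   \item{moffat}{\code{hsize}, \code{s}, \code{beta}; the profile
#'     \eqn{(1 + r^2/s^2)^{-\beta}}.}
#'   \item{identity}{no parameters; the unit operator.}
#' }
#'
#' @param family blur family name.
#' @param ... family-specific named parameters (see above).
#' @return a \linkS4class{BlurSpec}.
#' @examples
#' blurSpec("motion", length = 5, angle = 30)
#' @export
blurSpec <- function(family, ...) {
  dots <- list(...)
  params <- if (length(dots)) unlist(dots) else numeric(0)
  need <- switch(family,
    motion   = c("length"),
    gaussian = c("hsize", "sigma"),
    disk     = c("radius"),
    average  = c("hsize"),
    moffat   = c("hsize", "s", "beta"),
    identity = character(0),
    stop("unknown blur family: ", family))
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("blur family '", family, "' needs parameter(s): ",
         paste(miss, collapse = ", "))
  if (family == "motion" && !("angle" %in% names(params)))
    params <- c(params, angle = 0)
  chk <- params[setdiff(names(params), "angle")]
  if (any(!is.finite(chk)) || any(chk <= 0))
    stop("blur parameters must be strictly positive")
  new("BlurSpec", family = family, params = params)
}

## anti-aliased motion-blur line segment of a given length and angle
motionKernel <- function(len, angle) {
  if (len <= 1) return(matrix(1, 1, 1))
  half <- (len - 1) / 2
  th <- angle * pi / 180
  cth <- cos(th); sth <- sin(th)
  ## snap the axis-aligned cases exactly
  if (abs(cth) < 1e-12) cth <- 0
  if (abs(sth) < 1e-12) sth <- 0
  ext <- half + 1
  ei <- max(ceiling(abs(ext * sth)), 0)
  ej <- max(ceiling(abs(ext * cth)), 0)
  ii <- -ei:ei; jj <- -ej:ej
  ## x to the right (columns), y upward (negative row offset)
  x <- matrix(jj, length(ii), length(jj), byrow = TRUE)
  y <- matrix(-ii, length(ii), length(jj))
  s <- x * cth + y * sth       # position along the line
  d <- abs(-x * sth + y * cth) # distance from the line
  w <- clamp(half + 1 - abs(s), 0, 1) * clamp(1 - d, 0, 1)
  ## trim all-zero border rows/columns so the support is minimal
  nzr <- which(rowSums(w) > 0); nzc <- which(colSums(w) > 0)
  w <- w[min(nzr):max(nzr), min(nzc):max(nzc), drop = FALSE]
  w / sum(w)
}

diskKernel <- function(radius, super = 32L) {
  crad <- ceiling(radius - 0.5)
  side <- 2L * crad + 1L
  off <- seq_len(side) - (crad + 1L)
  sub <- (seq_len(super) - 0.5) / super - 0.5
  w <- matrix(0, side, side)
  for (a in seq_len(side)) {
    for (b in seq_len(side)) {
      xs <- off[a] + sub
      ys <- off[b] + sub
      w[a, b] <- mean(outer(xs^2, ys^2, `+`) <= radius^2)
    }
  }
  w / sum(w)
}

#' Realize a point spread function
#'
#' Turns a \linkS4class{BlurSpec} into a normalized \linkS4class{Psf}
#' emulating the MATLAB \code{fspecial} semantics for the corresponding
#' family. All kernels are nonnegative and sum to one.
#'
#' @param spec a \linkS4class{BlurSpec}, or a family name (then the
#'   family parameters are passed via \code{...}).
#' @param boundary convolution boundary rule, "periodic" (default; required
#'   by the solver) or "symmetric".
#' @param ... family parameters when \code{spec} is a character name.
#' @return a \linkS4class{Psf}.
#' @examples
#' makePsf("motion", length = 5, angle = 30)
#' makePsf(blurSpec("disk", radius = 5))
#' @export
makePsf <- function(spec, boundary = c("periodic", "symmetric"), ...) {
  boundary <- match.arg(boundary)
  if (is.character(spec)) spec <- blurSpec(spec, ...)
  stopifnot(is(spec, "BlurSpec"))
  p <- spec@params
  k <- switch(spec@family,
    identity = matrix(1, 1, 1),
    motion = motionKernel(p[["length"]], p[["angle"]]),
    gaussian = {
      h <- round(p[["hsize"]])
      off <- seq_len(h) - (h + 1) / 2
      w <- exp(-outer(off^2, off^2, `+`) / (2 * p[["sigma"]]^2))
      w / sum(w)
    },
    disk = diskKernel(p[["radius"]]),
    average = {
      h <- round(p[["hsize"]])
      matrix(1 / h^2, h, h)
    },
    moffat = {
      h <- round(p[["hsize"]])
      off <- seq_len(h) - (h + 1) / 2
      r2 <- outer(off^2, off^2, `+`)
      w <- (1 + r2 / p[["s"]]^2)^(-p[["beta"]])
      w / sum(w)
    })
  new("Psf", kernel = k, boundary = boundary)
}

#' @rdname accessors
setMethod("psfKernel", "Psf", function(x) x@kernel)

#' @rdname accessors
setMethod("psfBoundary", "Psf", function(x) x@boundary)

## periodic convolution of a matrix with a Psf kernel, via the FFT
blurMatrix <- function(u, psf) {
  m <- dim(u)
  if (psf@boundary == "periodic") {
    otf <- psf2otf(psf@kernel, m[1], m[2])
    ifft2Real(otf * fft2(u))
  } else {
    ## symmetric: reflect-pad by the kernel half-sizes, blur periodically
    ## on the padded field, crop back
    k <- psf@kernel
    h1 <- nrow(k) %/% 2L; h2 <- ncol(k) %/% 2L
    if (h1 >= m[1] || h2 >= m[2])
      stop("kernel is too large for symmetric padding of this image")
    ri <- c(rev(seq_len(h1)), seq_len(m[1]), m[1] - seq_len(h1) + 1L)
    ci <- c(rev(seq_len(h2)), seq_len(m[2]), m[2] - seq_len(h2) + 1L)
    up <- u[ri, ci, drop = FALSE]
    otf <- psf2otf(k, nrow(up), ncol(up))
    v <- ifft2Real(otf * fft2(up))
    v[h1 + seq_len(m[1]), h2 + seq_len(m[2]), drop = FALSE]
  }
}

#' @describeIn applyBlur single kernel applied to a bare matrix.
setMethod("applyBlur", signature("matrix", "Psf"), function(x, blur) {
  blurMatrix(x, blur)
})

#' @describeIn applyBlur single kernel applied channelwise to an image.
setMethod("applyBlur", signature("ImageGrid", "Psf"), function(x, blur) {
  p <- x@pixels
  if (length(dim(p)) == 2L) {
    imageGrid(blurMatrix(p, blur), nMax = x@nMax)
  } else {
    out <- p
    for (k in seq_len(dim(p)[3])) out[, , k] <- blurMatrix(p[, , k], blur)
    imageGrid(out, nMax = x@nMax)
  }
})

#' @describeIn applyBlur cross-channel kernel grid applied to a
#'   multichannel image: channel k of the output is
#'   \eqn{\sum_l \omega_{kl} K_{kl} * u^{(l)}}.
setMethod("applyBlur", signature("ImageGrid", "CrossChannelBlur"),
  function(x, blur) {
    m <- nrow(blur@weights)
    if (nChannels(x) != m)
      stop("image has ", nChannels(x), " channels but the blur couples ", m)
    p <- x@pixels
    out <- array(0, dim(p))
    for (k in seq_len(m)) {
      acc <- matrix(0, dim(p)[1], dim(p)[2])
      for (l in seq_len(m)) {
        w <- blur@weights[k, l]
        if (w == 0) next
        acc <- acc + w * blurMatrix(p[, , l], blur@kernels[[(k - 1) * m + l]])
      }
      out[, , k] <- acc
    }
    imageGrid(out, nMax = x@nMax)
  })

#' Describe a mean-one multiplicative noise field
#'
#' @param family "gamma", "rayleigh", "gaussian" or "speckle_variance".
#' @param L number of looks (gamma family); the field is Gamma(L, scale 1/L)
#'   with mean 1 and variance 1/L.
#' @param sigma2 variance (gaussian family), or the speckle variance for
#'   \code{"speckle_variance"}, which maps onto a Gamma field with
#'   \code{L = round(1/sigma2)}.
#' @param seed RNG seed; identical seeds give identical fields.
#' @return a \linkS4class{NoiseSpec}.
#' @examples
#' noiseSpec("gamma", L = 10, seed = 1)
#' @export
noiseSpec <- function(family, L = NA_real_, sigma2 = NA_real_,
                      seed = NA_real_) {
  if (family == "speckle_variance") {
    if (!is.finite(sigma2) || sigma2 <= 0) stop("'sigma2' must be > 0")
    L <- round(1 / sigma2)
    if (L < 1) stop("speckle variance ", sigma2, " maps to L < 1")
  }
  new("NoiseSpec", family = family, L = L, sigma2 = sigma2,
      seed = as.numeric(seed))
}

#' Sample a mean-one multiplicative noise field
#'
#' All families are normalized to unit mean: gamma is Gamma(shape L,
#' scale 1/L); rayleigh uses scale \eqn{\sqrt{2/\pi}} (so its mean
#' \eqn{\sigma_R\sqrt{\pi/2}} is one); gaussian is Normal(1, sigma2) clipped
#' to stay positive. \code{"speckle_variance"} draws the equivalent Gamma
#' field. Sampling is driven entirely by the seed recorded in \code{spec}.
#'
#' @param shape integer vector, length 2 (m1, m2) or 3 (m1, m2, channels).
#' @param spec a \linkS4class{NoiseSpec} with a finite seed.
#' @return a matrix or array of the requested shape.
#' @examples
#' eta <- sampleNoise(c(64, 64), noiseSpec("gamma", L = 10, seed = 7))
#' mean(eta)
#' @export
sampleNoise <- function(shape, spec) {
  stopifnot(is(spec, "NoiseSpec"))
  if (!is.finite(spec@seed))
    stop("'spec' must carry a finite seed (reproducibility contract)")
  shape <- as.integer(shape)
  n <- prod(shape)
  set.seed(spec@seed)
  eta <- switch(spec@family,
    gamma = stats::rgamma(n, shape = spec@L, rate = spec@L),
    speckle_variance = {
      L <- round(1 / spec@sigma2)
      stats::rgamma(n, shape = L, rate = L)
    },
    rayleigh = {
      sR <- sqrt(2 / pi)
      sR * sqrt(-2 * log(stats::runif(n)))
    },
    gaussian = pmax(1 + sqrt(spec@sigma2) * stats::rnorm(n), 1e-8))
  if (length(shape) == 2L) matrix(eta, shape[1], shape[2])
  else array(eta, shape)
}

#' Degrade an image by blur and multiplicative noise
#'
#' Applies the observation model \eqn{f = (Hu)\,\eta}: the image is blurred
#' by the point spread function, multiplied pixelwise by a mean-one noise
#' field, and floored at the positivity floor \code{epsPos(nMax)} so the
#' log fidelity stays finite. Multichannel images receive an independent
#' noise draw per channel from the same seeded stream.
#'
#' @param u clean \linkS4class{ImageGrid} (all pixels >= the positivity
#'   floor).
#' @param psf a \linkS4class{Psf} or \linkS4class{CrossChannelBlur}.
#' @param spec a \linkS4class{NoiseSpec} with a finite seed.
#' @return list with elements \code{image} (the degraded
#'   \linkS4class{ImageGrid}) and \code{noise} (the realized field
#'   \eqn{\eta}, for introspection).
#' @examples
#' u <- makeTestImage("phantom", n = 64)
#' d <- degradeImage(u, makePsf("identity"), noiseSpec("gamma", L = 10, seed = 1))
#' d$image
#' @export
degradeImage <- function(u, psf, spec) {
  stopifnot(is(u, "ImageGrid"))
  fl <- epsPos(u@nMax)
  b <- applyBlur(u, psf)
  eta <- sampleNoise(dim(b@pixels), spec)
  f <- pmax(b@pixels * eta, fl)
  list(image = imageGrid(f, nMax = u@nMax), noise = eta)
}

#' Build a cross-channel blur from the nine-kernel recipe
#'
#' Generates the nine kernels motion(11, 45), motion(21, 90),
#' motion(41, 135), gaussian(7, 5), gaussian(9, 5), gaussian(11, 5),
#' average(13), average(15), average(17); assigns them to the grid positions
#' K_11 ... K_33 by a seeded random permutation; and weights block (i, j)
#' by the entry \eqn{\omega_{ij}} of W. W = diag(3) gives pure
#' within-channel blurring (the off-diagonal blocks are zero operators).
#'
#' @param W 3 x 3 nonnegative weight matrix.
#' @param seed permutation seed.
#' @return a \linkS4class{CrossChannelBlur}.
#' @examples
#' makeCrossChannelBlur(diag(3), seed = 1)
#' @export
makeCrossChannelBlur <- function(W, seed) {
  W <- as.matrix(W)
  if (!all(dim(W) == c(3L, 3L)))
    stop("'W' must be 3 x 3 to match the nine-kernel recipe")
  specs <- list(
    blurSpec("motion", length = 11, angle = 45),
    blurSpec("motion", length = 21, angle = 90),
    blurSpec("motion", length = 41, angle = 135),
    blurSpec("gaussian", hsize = 7, sigma = 5),
    blurSpec("gaussian", hsize = 9, sigma = 5),
    blurSpec("gaussian", hsize = 11, sigma = 5),
    blurSpec("average", hsize = 13),
    blurSpec("average", hsize = 15),
    blurSpec("average", hsize = 17))
  set.seed(seed)
  ord <- sample.int(9L)
  kernels <- lapply(ord, function(i) makePsf(specs[[i]]))
  new("CrossChannelBlur", kernels = kernels, weights = W)
}

#' Cross-channel weight matrix used in the RGB restoration experiments
#'
#' @return the 3 x 3 row-stochastic-like weight matrix with rows
#'   (0.71, 0.15, 0.15), (0.12, 0.80, 0.20), (0.30, 0.30, 0.60).
#' @export
crossChannelWeights <- function() {
  matrix(c(0.71, 0.15, 0.15,
           0.12, 0.80, 0.20,
           0.30, 0.30, 0.60), 3, 3, byrow = TRUE)
}

## modified Shepp-Logan ellipse table: intensity, semiaxes a (x) / b (y),
## center (x0, y0), rotation phi in degrees
sheppLoganEllipses <- function() {
  matrix(c(
     1.0, 0.69,   0.92,   0,     0,      0,
    -0.8, 0.6624, 0.8740, 0,    -0.0184, 0,
    -0.2, 0.1100, 0.3100, 0.22,  0,    -18,
    -0.2, 0.1600, 0.4100,-0.22,  0,     18,
     0.1, 0.2100, 0.2500, 0,     0.35,   0,
     0.1, 0.0460, 0.0460, 0,     0.1,    0,
     0.1, 0.0460, 0.0460, 0,    -0.1,    0,
     0.1, 0.0460, 0.0230,-0.08, -0.605,  0,
     0.1, 0.0230, 0.0230, 0,    -0.606,  0,
     0.1, 0.0230, 0.0460, 0.06, -0.605,  0),
    ncol = 6, byrow = TRUE,
    dimnames = list(NULL, c("A", "a", "b", "x0", "y0", "phi")))
}

#' Generate a synthetic test image
#'
#' \describe{
#'   \item{phantom}{the modified Shepp-Logan head phantom (superposition of
#'     ten ellipses), rescaled from [0, 1] to [epsPos, nMax];}
#'   \item{constant}{all pixels at nMax/2;}
#'   \item{affine_ramp}{\eqn{u(i,j) = a\,i + b\,j + c}, by default spanning
#'     [epsPos, nMax];}
#'   \item{piecewise_constant}{a 4 x 4 block staircase spanning
#'     [epsPos, nMax].}
#' }
#' All kinds respect the positivity floor so the images can enter the
#' multiplicative-noise fidelity directly.
#'
#' @param kind image kind (see above).
#' @param n side length (square image), n >= 16.
#' @param nMax peak gray level.
#' @param a,b,c affine coefficients for \code{"affine_ramp"} (defaults fill
#'   the gray range).
#' @return an \linkS4class{ImageGrid}.
#' @examples
#' makeTestImage("phantom", n = 128)
#' @export
makeTestImage <- function(kind = c("phantom", "constant", "affine_ramp",
                                   "piecewise_constant"),
                          n, nMax = 255, a = NULL, b = NULL, c = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 16L) stop("'n' must be >= 16")
  fl <- epsPos(nMax)
  px <- switch(kind,
    constant = matrix(nMax / 2, n, n),
    affine_ramp = {
      if (is.null(a)) a <- (nMax - fl) / (2 * (n - 1))
      if (is.null(b)) b <- (nMax - fl) / (2 * (n - 1))
      if (is.null(c)) c <- fl
      ii <- matrix(0:(n - 1), n, n)
      jj <- matrix(0:(n - 1), n, n, byrow = TRUE)
      a * ii + b * jj + c
    },
    piecewise_constant = {
      lev <- seq(fl, nMax, length.out = 16)
      bi <- pmin((0:(n - 1)) %/% ceiling(n / 4), 3L)
      matrix(lev[outer(bi * 4L, bi, `+`) + 1L], n, n)
    },
    phantom = {
      E <- sheppLoganEllipses()
      ## MATLAB orientation: x runs left-right over columns, y runs
      ## bottom-up over rows, both spanning [-1, 1]
      g <- seq(-1, 1, length.out = n)
      x <- matrix(g, n, n, byrow = TRUE)
      y <- matrix(rev(g), n, n)
      v <- matrix(0, n, n)
      for (e in seq_len(nrow(E))) {
        phi <- E[e, "phi"] * pi / 180
        xr <- (x - E[e, "x0"]) * cos(phi) + (y - E[e, "y0"]) * sin(phi)
        yr <- -(x - E[e, "x0"]) * sin(phi) + (y - E[e, "y0"]) * cos(phi)
        v <- v + E[e, "A"] * ((xr / E[e, "a"])^2 + (yr / E[e, "b"])^2 <= 1)
      }
      v <- clamp(v, 0, 1)
      fl + (nMax - fl) * v
    })
  imageGrid(px, nMax = nMax)
}
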