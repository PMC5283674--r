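#' @include AllGenerics.R
NULL

#' Construct an ImageGrid
#'
#' @param pixels numeric matrix (grayscale) or m1 x m2 x m array
#'   (multichannel).
#' @param nMax peak gray level (default 255).
#' @return an \linkS4class{ImageGrid}.
#' @examples
#' img <- imageGrid(matrix(128, 32, 32))
#' img
#' @export
imageGrid <- function(pixels, nMax = 255) {
  if (is.matrix(pixels)) {
    storage.mode(pixels) <- "double"
  } else {
    pixels <- array(as.double(pixels), dim = dim(pixels))
  }
  new("ImageGrid", pixels = pixels, nMax = as.numeric(nMax))
}

#' @rdname accessors
setMethod("pixels", "ImageGrid", function(x) x@pixels)

#' @rdname accessors
setMethod("nMax", "ImageGrid", function(x) x@nMax)

#' @rdname accessors
setMethod("nChannels", "ImageGrid", function(x) {
  d <- dim(x@pixels)
  if (length(d) == 2L) 1L else d[3L]
})

#' @describeIn imageGrid spatial dimensions (m1, m2) of the image.
#' @param x an ImageGrid.
#' @export
setMethod("dim", "ImageGrid", function(x) dim(x@pixels)[1:2])

## extract channel k as a matrix
channelMatrix <- function(img, k = 1L) {
  p <- asPixels(img)
  if (length(dim(p)) == 2L) {
    if (k != 1L) stop("single-channel image has no channel ", k)
    p
  } else p[, , k]
}

setMethod("show", "ImageGrid", function(object) {
  d <- dim(object@pixels)
  ch <- nChannels(object)
  cat(sprintf("ImageGrid: %d x %d, %d channel%s, gray scale [0, %g]\n",
              d[1], d[2], ch, if (ch > 1) "s" else "", object@nMax))
  r <- range(object@pixels)
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              r[1], r[2], mean(object@pixels)))
})

setMethod("show", "Psf", function(object) {
  cat(sprintf("Psf: %d x %d kernel, %s boundary, sum = %.12g\n",
              nrow(object@kernel), ncol(object@kernel), object@boundary,
              sum(object@kernel)))
})

setMethod("show", "CrossChannelBlur", function(object) {
  m <- nrow(object@weights)
  cat(sprintf("CrossChannelBlur: %d x %d kernel grid\n", m, m))
  cat("  weights W:\n")
  print(round(object@weights, 4))
})

setMethod("show", "ShearletSystem", function(object) {
  cat(sprintf(
    "ShearletSystem: %d x %d, %d scale%s, %d bands (1 low-pass + %d directional)\n",
    object@shape[1], object@shape[2], object@nScales,
    if (object@nScales == 1L) "" else "s",
    length(object@filters), length(object@filters) - 1L))
})

setMethod("show", "ShearletCoeffs", function(object) {
  cat(sprintf("ShearletCoeffs: %d bands of %d x %d\n",
              length(object@bands), object@shape[1], object@shape[2]))
})

setMethod("show", "SolverConfig", function(object) {
  cat("SolverConfig:\n")
  cat(sprintf("  energy     lambda = %g, alpha = %g, gamma1 = %g, gamma0 = %g\n",
              object@lambda, object@alpha, object@gamma1, object@gamma0))
  cat(sprintf("  penalties  mu0 = %g, mu1 = %g, mu2 = %g, mu3 = %g, mu = %g\n",
              object@mu0, object@mu1, object@mu2, object@mu3, object@mu))
  cat(sprintf("  stopping   maxIter = %d, tol = %g\n", object@maxIter, object@tol))
  cat(sprintf("  shearlet   nScales = %d, penalizeLowpass = %s\n",
              object@nScales, object@penalizeLowpass))
})

setMethod("show", "RestorationResult", function(object) {
  cat(sprintf("RestorationResult: %s after %d iteration%s\n",
              if (object@converged) "converged" else "stopped at iteration cap",
              object@iterations, if (object@iterations == 1L) "" else "s"))
  show(object@image)
})

#' Accessors for RestorationResult
#'
#' @param x a \linkS4class{RestorationResult}.
#' @return \code{restoredImage}: the restored \linkS4class{ImageGrid};
#'   \code{solverHistory}: per-iteration diagnostics (energy, primal
#'   residuals, relative change); \code{converged}: logical.
#' @name RestorationResult-accessors
#' @export
restoredImage <- function(x) x@image

#' @rdname RestorationResult-accessors
#' @export
solverHistory <- function(x) x@history

#' @rdname RestorationResult-accessors
#' @export
converged <- function(x) x@converged
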