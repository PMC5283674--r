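#' @include AllClasses.R
NULL

#' Accessors for shearTGV classes
#'
#' \code{pixels} returns the raw intensity array of an \linkS4class{ImageGrid};
#' \code{nMax} its peak gray level; \code{nChannels} its channel count;
#' \code{psfKernel} and \code{psfBoundary} the kernel matrix and boundary rule
#' of a \linkS4class{Psf}; \code{filters}, \code{nScales} and
#' \code{systemShape} the components of a \linkS4class{ShearletSystem};
#' \code{bands} the coefficient stack of a \linkS4class{ShearletCoeffs}.
#'
#' @param x object to access.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases pixels nMax nChannels psfKernel psfBoundary filters nScales
#'   systemShape bands
#' @examples
#' img <- makeTestImage("constant", n = 16)
#' dim(pixels(img))
#' nMax(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("nMax", function(x) standardGeneric("nMax"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("psfKernel", function(x) standardGeneric("psfKernel"))

#' @rdname accessors
#' @export
setGeneric("psfBoundary", function(x) standardGeneric("psfBoundary"))

#' @rdname accessors
#' @export
setGeneric("filters", function(x) standardGeneric("filters"))

#' @rdname accessors
#' @export
setGeneric("nScales", function(x) standardGeneric("nScales"))

#' @rdname accessors
#' @export
setGeneric("systemShape", function(x) standardGeneric("systemShape"))

#' @rdname accessors
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))

#' Apply a blurring operator to an image
#'
#' Linear, mean-preserving convolution of an image with a normalized point
#' spread function (\linkS4class{Psf}) or with a cross-channel kernel grid
#' (\linkS4class{CrossChannelBlur}). With the default periodic boundary the
#' convolution is computed through the FFT and is exactly the operator H
#' that the restoration solver inverts; symmetric padding is available for
#' forward simulation only.
#'
#' @param x an \linkS4class{ImageGrid}, or a plain matrix (single channel).
#' @param blur a \linkS4class{Psf} or \linkS4class{CrossChannelBlur}.
#' @return an object of the same class as \code{x}.
#' @examples
#' u <- makeTestImage("phantom", n = 64)
#' h <- makePsf(blurSpec("gaussian", hsize = 7, sigma = 2))
#' f <- applyBlur(u, h)
#' @export
setGeneric("applyBlur", function(x, blur) standardGeneric("applyBlur"))

#' Forward and adjoint band-limited shearlet transform
#'
#' \code{shearletForward} computes the per-band coefficients
#' \eqn{SH_j(u) = F^{-1}(H_j \cdot F u)}; \code{shearletAdjoint} applies the
#' adjoint \eqn{\sum_j F^{-1}(H_j \cdot F c_j)}. Because the filters form a
#' Parseval frame, the adjoint inverts the forward transform exactly:
#' \code{shearletAdjoint(shearletForward(u, s), s)} reproduces \code{u} to
#' near machine precision.
#'
#' @param x an \linkS4class{ImageGrid} or matrix (forward), or a
#'   \linkS4class{ShearletCoeffs} (adjoint).
#' @param system a \linkS4class{ShearletSystem} built for the image shape.
#' @return \code{shearletForward}: a \linkS4class{ShearletCoeffs};
#'   \code{shearletAdjoint}: a matrix.
#' @examples
#' sys <- buildShearletSystem(64, 64, nScales = 2)
#' u <- pixels(makeTestImage("phantom", n = 64))
#' co <- shearletForward(u, sys)
#' max(abs(shearletAdjoint(co, sys) - u))
#' @export
setGeneric("shearletForward", function(x, system) standardGeneric("shearletForward"))

#' @rdname shearletForward
#' @export
setGeneric("shearletAdjoint", function(x, system) standardGeneric("shearletAdjoint"))
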