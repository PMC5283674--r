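#' @import methods
NULL

## Central data containers. All pixel data are stored as base arrays inside
## light S4 wrappers with validity checks; accessors live in the *-methods
## files. Intensities are kept on the [0, nMax] gray-level scale throughout
## the user-facing API.

#' ImageGrid: a strictly finite 2-D intensity field
#'
#' Container for a single- or multichannel 2-D image on the nominal gray
#' scale \eqn{[0, N_{max}]}. Single-channel images store an m1 x m2 matrix,
#' multichannel images an m1 x m2 x m array. Any image that enters the
#' multiplicative-noise fidelity term must additionally be bounded below by
#' the positivity floor \code{epsPos(nMax)} so that \eqn{\log(Hu)} and
#' \eqn{f/(Hu)} stay finite; constructors of degraded images enforce this.
#'
#' @slot pixels numeric matrix (m1 x m2) or array (m1 x m2 x m).
#' @slot nMax peak gray level, default 255.
#' @aliases ImageGrid
#' @exportClass ImageGrid
setClass("ImageGrid",
  representation(pixels = "array", nMax = "numeric"),
  prototype(pixels = array(0, c(1, 1)), nMax = 255),
  validity = function(object) {
    p <- object@pixels
    if (!(length(dim(p)) %in% c(2L, 3L)))
      return("'pixels' must be a 2-D matrix or a 3-D (row, col, channel) array")
    if (!all(is.finite(p)))
      return("'pixels' must be finite")
    if (length(object@nMax) != 1L || !is.finite(object@nMax) || object@nMax <= 0)
      return("'nMax' must be a single positive number")
    TRUE
  })

#' BlurSpec: parametric description of a point spread function
#'
#' @slot family one of "motion", "gaussian", "disk", "average", "moffat",
#'   "identity".
#' @slot params named numeric vector of family-specific parameters.
#' @aliases BlurSpec
#' @exportClass BlurSpec
setClass("BlurSpec",
  representation(family = "character", params = "numeric"),
  validity = function(object) {
    fams <- c("motion", "gaussian", "disk", "average", "moffat", "identity")
    if (length(object@family) != 1L || !(object@family %in% fams))
      return(paste0("'family' must be one of: ", paste(fams, collapse = ", ")))
    TRUE
  })

#' Psf: a realized, normalized convolution kernel
#'
#' Realizes the linear blurring operator H as a nonnegative kernel whose
#' weights sum to one (so constant images are preserved). Convolution is
#' periodic by default, which makes H diagonal in the Fourier domain; a
#' symmetric-padding variant is available for forward simulation only.
#'
#' @slot kernel nonnegative matrix summing to 1 (tolerance 1e-12).
#' @slot boundary "periodic" or "symmetric".
#' @aliases Psf
#' @exportClass Psf
setClass("Psf",
  representation(kernel = "matrix", boundary = "character"),
  prototype(boundary = "periodic"),
  validity = function(object) {
    k <- object@kernel
    if (any(!is.finite(k)) || any(k < 0))
      return("kernel weights must be finite and nonnegative")
    if (abs(sum(k) - 1) > 1e-12)
      return("kernel weights must sum to 1 (within 1e-12)")
    if (!(object@boundary %in% c("periodic", "symmetric")))
      return("'boundary' must be \"periodic\" or \"symmetric\"")
    TRUE
  })

#' CrossChannelBlur: an m x m grid of weighted kernels
#'
#' Channel k of the blurred image is \eqn{\sum_l \omega_{kl} K_{kl} * u^{(l)}};
#' each K_ij is a normalized \linkS4class{Psf} before weighting by the
#' corresponding entry of the weight matrix W.
#'
#' @slot kernels list of m^2 \linkS4class{Psf} objects in row-major (k, l)
#'   order.
#' @slot weights m x m nonnegative weight matrix W.
#' @aliases CrossChannelBlur
#' @exportClass CrossChannelBlur
setClass("CrossChannelBlur",
  representation(kernels = "list", weights = "matrix"),
  validity = function(object) {
    W <- object@weights
    if (nrow(W) != ncol(W)) return("'weights' must be square")
    if (any(!is.finite(W)) || any(W < 0))
      return("'weights' must be finite and nonnegative")
    if (length(object@kernels) != length(W))
      return("'kernels' must hold one Psf per entry of 'weights'")
    if (!all(vapply(object@kernels, is, logical(1), "Psf")))
      return("'kernels' must all be Psf objects")
    TRUE
  })

#' NoiseSpec: parametric description of a mean-one multiplicative noise field
#'
#' Families: \code{"gamma"} (number of looks L; Gamma(L, scale 1/L), variance
#' 1/L), \code{"rayleigh"} (Rayleigh rescaled to mean one), \code{"gaussian"}
#' (Normal(1, sigma2) clipped to be positive), and \code{"speckle_variance"}
#' (a Gamma field with L = round(1/sigma2), matching the "gamma noise of
#' variance sigma^2" convention used for speckle simulators).
#'
#' @slot family one of "gamma", "rayleigh", "gaussian", "speckle_variance".
#' @slot L number of looks (gamma family), integer-valued, >= 1.
#' @slot sigma2 variance (gaussian / speckle_variance families).
#' @slot seed RNG seed used by \code{\link{sampleNoise}}.
#' @aliases NoiseSpec
#' @exportClass NoiseSpec
setClass("NoiseSpec",
  representation(family = "character", L = "numeric", sigma2 = "numeric",
                 seed = "numeric"),
  prototype(L = NA_real_, sigma2 = NA_real_, seed = NA_real_),
  validity = function(object) {
    fams <- c("gamma", "rayleigh", "gaussian", "speckle_variance")
    if (length(object@family) != 1L || !(object@family %in% fams))
      return(paste0("'family' must be one of: ", paste(fams, collapse = ", ")))
    if (object@family == "gamma") {
      L <- object@L
      if (!is.finite(L) || L < 1 || abs(L - round(L)) > 1e-8)
        return("gamma noise needs an integer number of looks L >= 1")
    }
    if (object@family %in% c("gaussian", "speckle_variance")) {
      if (!is.finite(object@sigma2) || object@sigma2 <= 0)
        return("'sigma2' must be > 0")
    }
    TRUE
  })

#' ShearletSystem: a band-limited directional frame in the Fourier domain
#'
#' Holds the real frequency responses H_j of a Meyer-window, cone-adapted
#' band-limited shearlet-type system: band 1 is the low-pass (scaling)
#' filter, the remaining bands are directional, with the number of
#' directions doubling per scale. The responses form a Parseval frame:
#' \eqn{\sum_j H_j(\omega)^2 = 1} at every discrete frequency, so the
#' adjoint transform inverts the forward transform exactly.
#'
#' @slot filters list of real matrices, unshifted FFT frequency layout.
#' @slot nScales integer number of directional scales (0 = low-pass only).
#' @slot shape integer (m1, m2).
#' @aliases ShearletSystem
#' @exportClass ShearletSystem
setClass("ShearletSystem",
  representation(filters = "list", nScales = "integer", shape = "integer"),
  validity = function(object) {
    if (length(object@shape) != 2L) return("'shape' must be length 2")
    if (length(object@filters) < 1L) return("at least the low-pass filter is required")
    ok <- vapply(object@filters,
                 function(h) is.matrix(h) && all(dim(h) == object@shape),
                 logical(1))
    if (!all(ok)) return("all filters must be matrices of dimension 'shape'")
    s <- Reduce(`+`, lapply(object@filters, function(h) h * h))
    if (max(abs(s - 1)) > 1e-10)
      return("filters must satisfy the Parseval identity sum_j H_j^2 = 1 (1e-10)")
    TRUE
  })

#' ShearletCoeffs: per-band coefficient stack
#'
#' @slot bands list of real matrices, one per filter of the generating
#'   system (same order: low-pass first).
#' @slot shape integer (m1, m2).
#' @aliases ShearletCoeffs
#' @exportClass ShearletCoeffs
setClass("ShearletCoeffs",
  representation(bands = "list", shape = "integer"),
  validity = function(object) {
    ok <- vapply(object@bands,
                 function(b) is.matrix(b) && all(dim(b) == object@shape),
                 logical(1))
    if (!all(ok)) return("all bands must be matrices of dimension 'shape'")
    TRUE
  })

#' VectorField: per-pixel 2-vectors (gradient-like quantities)
#'
#' @slot v1,v2 m1 x m2 component matrices.
#' @aliases VectorField
#' @exportClass VectorField
setClass("VectorField",
  representation(v1 = "matrix", v2 = "matrix"),
  validity = function(object) {
    if (!all(dim(object@v1) == dim(object@v2)))
      return("components must share a shape")
    if (!all(is.finite(object@v1)) || !all(is.finite(object@v2)))
      return("components must be finite")
    TRUE
  })

#' SymTensorField: per-pixel symmetric 2 x 2 tensors
#'
#' Only the three distinct planes are stored; w21 = w12 is structural.
#' Norms over this field count the off-diagonal twice (true Frobenius norm).
#'
#' @slot w11,w12,w22 m1 x m2 component matrices.
#' @aliases SymTensorField
#' @exportClass SymTensorField
setClass("SymTensorField",
  representation(w11 = "matrix", w12 = "matrix", w22 = "matrix"),
  validity = function(object) {
    d <- dim(object@w11)
    if (!all(dim(object@w12) == d) || !all(dim(object@w22) == d))
      return("components must share a shape")
    if (!all(is.finite(object@w11)) || !all(is.finite(object@w12)) ||
        !all(is.finite(object@w22)))
      return("components must be finite")
    TRUE
  })

#' SolverConfig: every tunable of the restoration energy and its ADMM solver
#'
#' See \code{\link{solverConfig}} for the meaning, units and defaults of
#' each slot.
#'
#' @slot lambda shearlet-sparsity weight.
#' @slot alpha quadratic-fidelity weight (coercivity requires alpha >= 26/9).
#' @slot gamma0,gamma1 TGV2 second/first-order weights.
#' @slot mu0,mu1,mu2,mu3 quadratic penalty weights of the ADMM splits
#'   (fidelity anchor t = Hu, shearlet, gradient, symmetric-gradient).
#' @slot mu dual-ascent step.
#' @slot beta alias accepted for the augmented-penalty parameter; mapped onto
#'   the dual step (the update equations never use it independently).
#' @slot maxIter iteration cap.
#' @slot tol relative-change stopping threshold.
#' @slot nScales shearlet scales.
#' @slot penalizeLowpass logical; whether the l1 penalty includes the
#'   low-pass band.
#' @slot innerNewton max damped-Newton steps of the pointwise fidelity prox.
#' @slot innerSweeps (p, u) alternations per multichannel subproblem.
#' @slot epsPosRel positivity floor relative to nMax.
#' @slot seed RNG seed recorded with the run.
#' @aliases SolverConfig
#' @exportClass SolverConfig
setClass("SolverConfig",
  representation(lambda = "numeric", alpha = "numeric",
                 gamma0 = "numeric", gamma1 = "numeric",
                 mu0 = "numeric", mu1 = "numeric", mu2 = "numeric",
                 mu3 = "numeric", mu = "numeric", beta = "numeric",
                 maxIter = "integer", tol = "numeric", nScales = "integer",
                 penalizeLowpass = "logical", innerNewton = "integer",
                 innerSweeps = "integer", epsPosRel = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    pos <- c(lambda = object@lambda, alpha = object@alpha,
             gamma0 = object@gamma0, gamma1 = object@gamma1,
             mu0 = object@mu0, mu1 = object@mu1, mu2 = object@mu2,
             mu3 = object@mu3, mu = object@mu, tol = object@tol,
             epsPosRel = object@epsPosRel)
    if (any(!is.finite(pos)) || any(pos <= 0))
      return("all weights, penalty parameters and tolerances must be > 0")
    if (object@maxIter < 1L) return("'maxIter' must be >= 1")
    if (object@nScales < 1L) return("'nScales' must be >= 1")
    TRUE
  })

#' ADMMState: all primal and dual variables of the splitting
#'
#' Internal bookkeeping object: primal u, p, per-band coefficients x_j,
#' vector split y, tensor split z, fidelity split t, their (scaled) dual
#' variables, and the iteration history.
#'
#' @slot u matrix, current image iterate (unit intensity scale).
#' @slot p \linkS4class{VectorField}.
#' @slot x,xd lists of per-band matrices (primal / dual).
#' @slot y,yd \linkS4class{VectorField} (primal / dual).
#' @slot z,zd \linkS4class{SymTensorField} (primal / dual).
#' @slot t,td matrices for the fidelity split t = Hu (primal / dual).
#' @slot iter iteration counter.
#' @slot history data.frame of per-iteration energy, residuals and relative
#'   change.
#' @aliases ADMMState
#' @exportClass ADMMState
setClass("ADMMState",
  representation(u = "matrix", p = "VectorField",
                 x = "list", xd = "list",
                 y = "VectorField", yd = "VectorField",
                 z = "SymTensorField", zd = "SymTensorField",
                 t = "matrix", td = "matrix",
                 iter = "integer", history = "data.frame"))

#' RestorationResult: restored image plus solver diagnostics
#'
#' @slot image \linkS4class{ImageGrid}, the restored image on the original
#'   gray scale, clipped to [0, nMax].
#' @slot iterations number of outer ADMM iterations performed.
#' @slot converged logical; TRUE if the relative-change criterion was met
#'   before the iteration cap.
#' @slot history data.frame with one row per iteration: energy, primal
#'   residuals of the three constraint groups, relative change of u.
#' @slot config the \linkS4class{SolverConfig} used.
#' @aliases RestorationResult
#' @exportClass RestorationResult
setClass("RestorationResult",
  representation(image = "ImageGrid", iterations = "integer",
                 converged = "logical", history = "data.frame",
                 config = "SolverConfig"))
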