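#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Discrete first/second-order difference machinery for TGV^2. Boundary rule:
## periodic differences throughout, matching the periodic convolution, so all
## operators are diagonal in the Fourier domain and adjointness is exact.
## Pixel spacing h = 1. Convention: x = first index (rows), y = second
## (columns); gradients use forward differences, the symmetrized gradient and
## div1 backward differences, div2 forward differences, which makes
## (div1)* = -grad and (div2)* = -symGrad hold exactly.
## ---------------------------------------------------------------------------

#' Construct a per-pixel 2-vector field
#'
#' @param v1,v2 component matrices of equal shape.
#' @return a \linkS4class{VectorField}.
#' @export
vectorField <- function(v1, v2) new("VectorField", v1 = v1, v2 = v2)

#' Construct a per-pixel symmetric 2 x 2 tensor field
#'
#' @param w11,w12,w22 component matrices of equal shape (w21 = w12 is
#'   implicit).
#' @return a \linkS4class{SymTensorField}.
#' @export
symTensorField <- function(w11, w12, w22)
  new("SymTensorField", w11 = w11, w12 = w12, w22 = w22)

## periodic forward/backward differences along rows (x) and columns (y)
dxPlus  <- function(u) circShift(u, -1L, 0L) - u
dyPlus  <- function(u) circShift(u, 0L, -1L) - u
dxMinus <- function(u) u - circShift(u, 1L, 0L)
dyMinus <- function(u) u - circShift(u, 0L, 1L)

#' Discrete gradient, symmetrized gradient and divergences
#'
#' The four linear operators of the second-order TGV machinery, with
#' periodic boundary: \code{imageGradient} maps an image to the forward
#' difference field \eqn{(\partial_x^+ u, \partial_y^+ u)};
#' \code{symGradient} maps a vector field to the symmetric tensor with
#' diagonal \eqn{(\partial_x^- v_1, \partial_y^- v_2)} and off-diagonal
#' \eqn{\frac12(\partial_y^- v_1 + \partial_x^- v_2)};
#' \code{divergence1} and \code{divergence2} are their negative adjoints:
#' \eqn{\langle \nabla u, v\rangle = -\langle u, \mathrm{div}_1 v\rangle}
#' and \eqn{\langle \bar\varepsilon(v), w\rangle = -\langle v,
#' \mathrm{div}_2 w\rangle} (with the tensor inner product counting the
#' off-diagonal twice).
#'
#' @param u image matrix (or single-channel \linkS4class{ImageGrid}).
#' @param v a \linkS4class{VectorField}.
#' @param w a \linkS4class{SymTensorField}.
#' @return \code{imageGradient}: a VectorField; \code{symGradient}: a
#'   SymTensorField; \code{divergence1}: a matrix; \code{divergence2}: a
#'   VectorField.
#' @examples
#' u <- pixels(makeTestImage("phantom", n = 32))
#' g <- imageGradient(u)
#' max(abs(divergence1(g)))  # discrete Laplacian of u
#' @name tgv-operators
NULL

#' @rdname tgv-operators
#' @export
imageGradient <- function(u) {
  u <- asPixels(u)
  vectorField(dxPlus(u), dyPlus(u))
}

#' @rdname tgv-operators
#' @export
symGradient <- function(v) {
  stopifnot(is(v, "VectorField"))
  symTensorField(dxMinus(v@v1),
                 0.5 * (dyMinus(v@v1) + dxMinus(v@v2)),
                 dyMinus(v@v2))
}

#' @rdname tgv-operators
#' @export
divergence1 <- function(v) {
  stopifnot(is(v, "VectorField"))
  dxMinus(v@v1) + dyMinus(v@v2)
}

#' @rdname tgv-operators
#' @export
divergence2 <- function(w) {
  stopifnot(is(w, "SymTensorField"))
  vectorField(dxPlus(w@w11) + dyPlus(w@w12),
              dxPlus(w@w12) + dyPlus(w@w22))
}

## l1-type norms: sum over pixels of the pointwise l2 / Frobenius norm
## (off-diagonal counted twice in the Frobenius norm)
vecNormL1 <- function(v) sum(sqrt(v@v1^2 + v@v2^2))
tenNormL1 <- function(w) sum(sqrt(w@w11^2 + 2 * w@w12^2 + w@w22^2))

## Fourier symbols of the 2 x 2 operator mu2 I + mu3 symGrad* symGrad
## acting on vector fields (used by the p-subproblem solves); entries of the
## Hermitian matrix per frequency
symGradNormalSymbols <- function(sym) {
  ax2 <- Mod(sym$dxm)^2
  ay2 <- Mod(sym$dym)^2
  list(M11 = ax2 + 0.5 * ay2,
       M22 = ay2 + 0.5 * ax2,
       M12 = 0.5 * Conj(sym$dym) * sym$dxm)
}

#' Approximate second-order TGV value of an image
#'
#' Evaluates \eqn{TGV^2_\gamma(u) = \min_v \gamma_1\|\nabla u - v\|_1 +
#' \gamma_0\|\bar\varepsilon(v)\|_1} by a short internal ADMM over the
#' auxiliary vector field (splitting both l1 terms, with the quadratic
#' v-subproblem solved exactly in the Fourier domain). Diagnostic use: the
#' restoration solver carries the auxiliary field explicitly and never calls
#' this. The value is exactly zero on affine images (v = gradient attains
#' zero in both terms) and bounded above by \eqn{\gamma_1 \|\nabla u\|_1}
#' (v = 0 is feasible).
#'
#' @param u image matrix or single-channel \linkS4class{ImageGrid}.
#' @param gamma0 weight of the second-order term, > 0.
#' @param gamma1 weight of the first-order term, > 0.
#' @param nIter inner iterations (default 200).
#' @return nonnegative scalar.
#' @examples
#' tgv2Value(pixels(makeTestImage("affine_ramp", n = 32)), 2, 1)
#' @export
tgv2Value <- function(u, gamma0 = 2, gamma1 = 1, nIter = 200L) {
  if (gamma0 <= 0 || gamma1 <= 0) stop("TGV weights must be > 0")
  u <- asPixels(u)
  m <- dim(u)
  g <- imageGradient(u)
  sym <- diffSymbols(m[1], m[2])
  Msym <- symGradNormalSymbols(sym)
  ## per-frequency inverse of I + symGrad*symGrad (Hermitian 2x2)
  A11 <- 1 + Msym$M11; A22 <- 1 + Msym$M22; A12 <- Msym$M12
  det <- Re(A11 * A22) - Mod(A12)^2
  zero <- matrix(0, m[1], m[2])
  v <- vectorField(zero, zero)
  yd1 <- yd2 <- zd11 <- zd12 <- zd22 <- zero
  obj <- function(v) {
    ev <- symGradient(v)
    gamma1 * vecNormL1(vectorField(g@v1 - v@v1, g@v2 - v@v2)) +
      gamma0 * tenNormL1(ev)
  }
  best <- obj(v)  # v = 0 start: gamma1 * ||grad u||_1, always feasible
  for (it in seq_len(nIter)) {
    ## split updates: y ~ grad u - v, z ~ symGrad v
    ey <- vectorField(g@v1 - v@v1 + yd1, g@v2 - v@v2 + yd2)
    y <- shrink2(ey, gamma1)
    ev <- symGradient(v)
    ez <- symTensorField(ev@w11 + zd11, ev@w12 + zd12, ev@w22 + zd22)
    z <- shrinkF(ez, gamma0)
    ## v-subproblem: (I + symGrad* symGrad) v = (grad u - cy) - div2(cz)
    cy1 <- y@v1 - yd1; cy2 <- y@v2 - yd2
    cz <- symTensorField(z@w11 - zd11, z@w12 - zd12, z@w22 - zd22)
    d2 <- divergence2(cz)
    r1 <- fft2(g@v1 - cy1 - d2@v1)
    r2 <- fft2(g@v2 - cy2 - d2@v2)
    v1h <- (A22 * r1 - A12 * r2) / det
    v2h <- (A11 * r2 - Conj(A12) * r1) / det
    v <- vectorField(ifft2Real(v1h), ifft2Real(v2h))
    ## dual ascent
    yd1 <- yd1 + (g@v1 - v@v1 - y@v1)
    yd2 <- yd2 + (g@v2 - v@v2 - y@v2)
    ev <- symGradient(v)
    zd11 <- zd11 + (ev@w11 - z@w11)
    zd12 <- zd12 + (ev@w12 - z@w12)
    zd22 <- zd22 + (ev@w22 - z@w22)
    best <- min(best, obj(v))
  }
  best
}
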