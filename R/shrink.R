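#' @include tgv.R
NULL

#' Soft-thresholding (proximal) operators
#'
#' The three closed-form proximal maps used by the ADMM splitting:
#' \code{shrink1} is the scalar soft threshold
#' \eqn{\mathrm{sgn}(\nu)\max(|\nu| - \sigma, 0)} applied elementwise
#' (the prox of \eqn{\sigma|\cdot|}); \code{shrink2} shrinks the pointwise
#' Euclidean norm of a 2-vector field towards zero, clamping vectors with
#' \eqn{\|a\|_2 \le \mu} to zero (the prox of \eqn{\mu\|\cdot\|_2});
#' \code{shrinkF} does the same on symmetric 2 x 2 tensors under the
#' Frobenius norm with the off-diagonal counted twice.
#'
#' @param v numeric array (\code{shrink1}), \linkS4class{VectorField}
#'   (\code{shrink2}) or \linkS4class{SymTensorField} (\code{shrinkF}).
#' @param sigma,mu threshold, >= 0.
#' @return object of the same class as \code{v}.
#' @examples
#' shrink1(c(2, -0.3), 0.5)
#' shrink2(vectorField(matrix(3), matrix(4)), 1)
#' @name shrink
NULL

#' @rdname shrink
#' @export
shrink1 <- function(v, sigma) {
  if (sigma < 0) stop("threshold must be >= 0")
  sign(v) * pmax(abs(v) - sigma, 0)
}

#' @rdname shrink
#' @export
shrink2 <- function(v, mu) {
  if (mu < 0) stop("threshold must be >= 0")
  stopifnot(is(v, "VectorField"))
  nrm <- sqrt(v@v1^2 + v@v2^2)
  sc <- ifelse(nrm > mu, (nrm - mu) / nrm, 0)
  vectorField(sc * v@v1, sc * v@v2)
}

#' @rdname shrink
#' @export
shrinkF <- function(v, mu) {
  if (mu < 0) stop("threshold must be >= 0")
  stopifnot(is(v, "SymTensorField"))
  nrm <- sqrt(v@w11^2 + 2 * v@w12^2 + v@w22^2)
  sc <- ifelse(nrm > mu, (nrm - mu) / nrm, 0)
  symTensorField(sc * v@w11, sc * v@w12, sc * v@w22)
}
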