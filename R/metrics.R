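#' @include ImageGrid-methods.R
NULL

## pixelwise arrays for metric computations; shapes must agree
metricPair <- function(uhat, u) {
  a <- asPixels(uhat); b <- asPixels(u)
  if (!all(dim(a) == dim(b)))
    stop("images must share a shape: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  list(a = as.numeric(a), b = as.numeric(b))
}

#' Restoration quality metrics
#'
#' The four measures used to score restorations against the clean
#' reference:
#' \describe{
#'   \item{psnr}{\eqn{10\log_{10}(N^2 m_1 m_2 / \sum(\hat u - u)^2)} in dB,
#'     with N the peak gray level; identical images give \code{Inf}.}
#'   \item{ssimGlobal}{a single global structural-similarity statistic
#'     computed from whole-image means, variances and covariance (not the
#'     windowed SSIM of common practice), with stabilizers
#'     \eqn{a_1 = (0.01 N)^2}, \eqn{a_2 = (0.03 N)^2}; equals 1 iff the
#'     images coincide.}
#'   \item{relErr}{\eqn{\|\hat u - u\|_2^2 / \|u\|_2^2} (squared ratio;
#'     set \code{squared = FALSE} for the root ratio).}
#'   \item{snr}{\eqn{10\log_{10}(\|u - \bar u\|_2^2 / \|u - \hat u\|_2^2)}
#'     in dB, with \eqn{\bar u} the mean intensity of u; requires a
#'     non-constant reference.}
#' }
#'
#' @param uhat restored image (\linkS4class{ImageGrid} or array).
#' @param u clean reference, same shape.
#' @param nMaxVal peak gray level N (default 255).
#' @param a1,a2 SSIM stabilizers (defaults \eqn{(0.01N)^2}, \eqn{(0.03N)^2}).
#' @param squared report relErr as the squared ratio (default TRUE).
#' @return a scalar.
#' @examples
#' u <- pixels(makeTestImage("phantom", n = 64))
#' psnr(u + 2, u)
#' @name metrics
NULL

#' @rdname metrics
#' @export
psnr <- function(uhat, u, nMaxVal = 255) {
  pr <- metricPair(uhat, u)
  sse <- sum((pr$a - pr$b)^2)
  if (sse == 0) return(Inf)
  10 * log10(nMaxVal^2 * length(pr$a) / sse)
}

#' @rdname metrics
#' @export
ssimGlobal <- function(uhat, u, nMaxVal = 255,
                       a1 = (0.01 * nMaxVal)^2, a2 = (0.03 * nMaxVal)^2) {
  if (a1 <= 0 || a2 <= 0) stop("SSIM stabilizers must be > 0")
  pr <- metricPair(uhat, u)
  n <- length(pr$a)
  ma <- mean(pr$a); mb <- mean(pr$b)
  va <- sum((pr$a - ma)^2) / n
  vb <- sum((pr$b - mb)^2) / n
  cab <- sum((pr$a - ma) * (pr$b - mb)) / n
  ((2 * ma * mb + a1) * (2 * cab + a2)) /
    ((ma^2 + mb^2 + a1) * (va + vb + a2))
}

#' @rdname metrics
#' @export
relErr <- function(uhat, u, squared = TRUE) {
  pr <- metricPair(uhat, u)
  den <- sum(pr$b^2)
  if (den == 0) stop("relative error undefined for a zero reference")
  r <- sum((pr$a - pr$b)^2) / den
  if (squared) r else sqrt(r)
}

#' @rdname metrics
#' @export
snr <- function(uhat, u) {
  pr <- metricPair(uhat, u)
  num <- sum((pr$b - mean(pr$b))^2)
  if (num == 0) stop("SNR undefined for a constant reference")
  den <- sum((pr$b - pr$a)^2)
  if (den == 0) return(Inf)
  10 * log10(num / den)
}
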