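#' @include shrink.R shearlet.R degrade.R
NULL

#' Configure the restoration energy and its ADMM solver
#'
#' The energy minimized for a degraded image f (on its native gray scale)
#' is
#' \deqn{E(u, p) = \langle\log(Hu), 1\rangle + \langle f/(Hu), 1\rangle +
#'   \alpha\|Hu/f - 1\|_2^2 + \lambda\sum_j\|SH_j(u)\|_1 +
#'   \gamma_1\|\nabla u - p\|_1 + \gamma_0\|\bar\varepsilon(p)\|_1.}
#' The first three terms are the Gamma-MAP fidelity plus its convexifying
#' quadratic; the \eqn{\lambda} term enforces shearlet sparsity; the last two
#' are the second-order TGV penalty carried with an explicit auxiliary field
#' p. ADMM splits every nonsmooth term (and the fidelity through t = Hu)
#' with quadratic penalties mu1, mu2, mu3 (and mu0 for the fidelity split)
#' and dual-ascent step mu.
#'
#' @param lambda shearlet-sparsity weight; useful range about [1.5, 10] on
#'   the [0, 255] gray scale.
#' @param alpha quadratic-fidelity weight; the fidelity is convex and the
#'   energy coercive for alpha >= 26/9, and a warning is issued below that
#'   bound.
#' @param gamma0,gamma1 TGV2 weights (second / first order).
#' @param mu0,mu1,mu2,mu3 quadratic penalty weights of the ADMM splits
#'   (t = Hu, x_j = SH_j u, y = grad u - p, z = symGrad p).
#' @param mu dual-ascent step (default 1, the standard scaled-dual step).
#' @param beta optional alias for the augmented-penalty parameter; if given
#'   it overrides \code{mu} (the update equations use a single step).
#' @param maxIter outer iteration cap (typical runs use 100-700).
#' @param tol relative-change stopping threshold
#'   \eqn{\|u^{n+1}-u^n\|_2/\|u^n\|_2 \le} tol (default 2e-5).
#' @param nScales shearlet scales (default 4).
#' @param penalizeLowpass include the low-pass band in the l1 penalty
#'   (default TRUE; set FALSE to leave local means anchored by the data
#'   term alone, which also makes constant images exact fixed points).
#' @param innerNewton damped-Newton step cap of the pointwise fidelity prox.
#' @param innerSweeps (t, u, p) alternations inside
#'   \code{\link{solveUpSubproblem}} and the multichannel subproblem.
#' @param epsPosRel positivity floor relative to the peak gray level.
#' @param seed seed recorded with the run (the solver itself is
#'   deterministic).
#' @return a \linkS4class{SolverConfig}.
#' @examples
#' solverConfig(lambda = 3, maxIter = 200)
#' @export
solverConfig <- function(lambda = 5, alpha = 3, gamma0 = 2, gamma1 = 1,
                         mu0 = 10, mu1 = 10, mu2 = 10, mu3 = 10, mu = 1,
                         beta = NULL, maxIter = 400L, tol = 2e-5,
                         nScales = 4L, penalizeLowpass = TRUE,
                         innerNewton = 20L, innerSweeps = 2L,
                         epsPosRel = 1e-3, seed = NA_real_) {
  if (!is.null(beta)) mu <- beta
  if (alpha < 26 / 9)
    warning("alpha = ", alpha, " is below the coercivity bound 26/9 = ",
            format(26 / 9, digits = 4),
            "; existence/uniqueness of the minimizer is not guaranteed")
  new("SolverConfig", lambda = lambda, alpha = alpha, gamma0 = gamma0,
      gamma1 = gamma1, mu0 = mu0, mu1 = mu1, mu2 = mu2, mu3 = mu3, mu = mu,
      beta = if (is.null(beta)) mu else beta,
      maxIter = as.integer(maxIter), tol = tol, nScales = as.integer(nScales),
      penalizeLowpass = penalizeLowpass,
      innerNewton = as.integer(innerNewton),
      innerSweeps = as.integer(innerSweeps),
      epsPosRel = epsPosRel, seed = as.numeric(seed))
}

## low-pass-only Parseval system for images too small for directional bands
trivialShearletSystem <- function(m1, m2) {
  new("ShearletSystem", filters = list(matrix(1, m1, m2)),
      nScales = 0L, shape = c(as.integer(m1), as.integer(m2)))
}

## pointwise fidelity phi(t) = log t + f/t + alpha (t/f - 1)^2 and its prox
## prox_{phi/mu0}(c) by damped Newton; strictly convex for alpha >= 1/54
proxFidelity <- function(cc, f, alpha, mu0, eps, maxNewton = 20L) {
  t <- pmax(cc, eps)
  for (k in seq_len(maxNewton)) {
    g <- 1 / t - f / t^2 + 2 * alpha * (t / f - 1) / f + mu0 * (t - cc)
    h <- -1 / t^2 + 2 * f / t^3 + 2 * alpha / f^2 + mu0
    step <- g / pmax(h, 1e-12)
    ## damping: never lose more than half the current value (keeps t > 0)
    t <- pmax(t - step, t / 2)
    if (max(abs(g)) < 1e-11 * (1 + mu0) * max(1, max(abs(cc)))) break
  }
  g <- 1 / t - f / t^2 + 2 * alpha * (t / f - 1) / f + mu0 * (t - cc)
  if (max(abs(g)) > 1e-6 * (1 + mu0) * max(1, max(abs(cc))))
    stop("fidelity prox Newton did not converge (max residual ",
         format(max(abs(g))), "); inspect alpha/mu0 scaling")
  t
}

## frequency-domain machinery shared by the solvers -------------------------

## precompute the per-frequency inverse of the Hermitian 3x3 (u, p1, p2)
## system matrix
upSystemInverse <- function(otf2, sym, Msym, cfg) {
  mu0 <- cfg@mu0; mu1 <- cfg@mu1; mu2 <- cfg@mu2; mu3 <- cfg@mu3
  a11 <- mu0 * otf2 + mu1 + mu2 * sym$lap + 0i
  a12 <- -mu2 * Conj(sym$dxp); a13 <- -mu2 * Conj(sym$dyp)
  a21 <- Conj(a12); a31 <- Conj(a13)
  a22 <- mu2 + mu3 * Msym$M11 + 0i
  a33 <- mu2 + mu3 * Msym$M22 + 0i
  a23 <- mu3 * Msym$M12; a32 <- Conj(a23)
  cof11 <- a22 * a33 - a23 * a32
  cof12 <- -(a21 * a33 - a23 * a31)
  cof13 <- a21 * a32 - a22 * a31
  cof21 <- -(a12 * a33 - a13 * a32)
  cof22 <- a11 * a33 - a13 * a31
  cof23 <- -(a11 * a32 - a12 * a31)
  cof31 <- a12 * a23 - a13 * a22
  cof32 <- -(a11 * a23 - a13 * a21)
  cof33 <- a11 * a22 - a12 * a21
  det <- a11 * cof11 + a12 * cof12 + a13 * cof13
  list(B11 = cof11 / det, B12 = cof21 / det, B13 = cof31 / det,
       B21 = cof12 / det, B22 = cof22 / det, B23 = cof32 / det,
       B31 = cof13 / det, B32 = cof23 / det, B33 = cof33 / det)
}

## assemble the three Fourier-domain right-hand sides of the (u, p) system
upRhs <- function(otfc, Fx, cy, cz, ct, sym, cfg) {
  d2 <- divergence2(cz)
  r1 <- cfg@mu0 * otfc * fft2(ct) + cfg@mu1 * Fx +
    cfg@mu2 * (Conj(sym$dxp) * fft2(cy@v1) + Conj(sym$dyp) * fft2(cy@v2))
  r2 <- fft2(-cfg@mu2 * cy@v1 - cfg@mu3 * d2@v1)
  r3 <- fft2(-cfg@mu2 * cy@v2 - cfg@mu3 * d2@v2)
  list(r1 = r1, r2 = r2, r3 = r3)
}

applyUpInverse <- function(B, r) {
  list(u = ifft2Real(B$B11 * r$r1 + B$B12 * r$r2 + B$B13 * r$r3),
       p1 = ifft2Real(B$B21 * r$r1 + B$B22 * r$r2 + B$B23 * r$r3),
       p2 = ifft2Real(B$B31 * r$r1 + B$B32 * r$r2 + B$B33 * r$r3))
}

#' Evaluate the restoration energy
#'
#' Computes the discrete energy term by term on the arrays as given (no
#' internal rescaling): \eqn{\sum\log(Hu) + \sum f/(Hu) +
#' \alpha\sum(Hu/f - 1)^2 + \lambda\sum_j\|SH_j(u)\|_1 +
#' \gamma_1\|\nabla u - p\|_1 + \gamma_0\|\bar\varepsilon(p)\|_1}.
#' Whether the low-pass band enters the \eqn{\lambda} sum follows
#' \code{cfg@penalizeLowpass}.
#'
#' @param u candidate image (matrix or single-channel ImageGrid).
#' @param p auxiliary \linkS4class{VectorField} (NULL for the zero field).
#' @param f observed image, all entries > 0.
#' @param psf \linkS4class{Psf} realizing H, or NULL for the identity.
#' @param cfg a \linkS4class{SolverConfig}.
#' @param system optional prebuilt \linkS4class{ShearletSystem}; built on
#'   demand when lambda > 0 (images smaller than 32 x 32 fall back to the
#'   low-pass-only system).
#' @return scalar energy value.
#' @examples
#' f <- matrix(1, 16, 16)
#' cfg <- solverConfig(lambda = 1e-9, gamma0 = 1e-9, gamma1 = 1e-9)
#' m4Energy(f, NULL, f, NULL, cfg)  # = number of pixels (log 1 + 1 + 0)
#' @export
m4Energy <- function(u, p, f, psf = NULL, cfg = solverConfig(),
                     system = NULL) {
  u <- asPixels(u); f <- asPixels(f)
  Hu <- if (is.null(psf)) u else applyBlur(u, psf)
  if (any(Hu <= 0) || any(f <= 0))
    stop("energy undefined: Hu and f must be strictly positive")
  if (is.null(p)) {
    zero <- matrix(0, nrow(u), ncol(u))
    p <- vectorField(zero, zero)
  }
  data <- sum(log(Hu)) + sum(f / Hu) + cfg@alpha * sum((Hu / f - 1)^2)
  shear <- 0
  if (cfg@lambda > 0) {
    if (is.null(system)) {
      system <- if (min(dim(u)) >= 32) {
        buildShearletSystem(nrow(u), ncol(u), cfg@nScales)
      } else trivialShearletSystem(nrow(u), ncol(u))
    }
    co <- shearletForward(u, system)@bands
    jj <- if (cfg@penalizeLowpass) seq_along(co) else seq_along(co)[-1L]
    shear <- cfg@lambda * sum(vapply(co[jj], function(b) sum(abs(b)),
                                     numeric(1)))
  }
  g <- imageGradient(u)
  data + shear +
    cfg@gamma1 * vecNormL1(vectorField(g@v1 - p@v1, g@v2 - p@v2)) +
    cfg@gamma0 * tenNormL1(symGradient(p))
}

## energy from solver-cached quantities (unit scale, inside the main loop)
energyFromCache <- function(Hu, f, SHu, gu, p, ep, cfg, eps) {
  Hs <- pmax(Hu, eps)
  jj <- if (cfg@penalizeLowpass) seq_along(SHu) else seq_along(SHu)[-1L]
  sum(log(Hs)) + sum(f / Hs) + cfg@alpha * sum((Hs / f - 1)^2) +
    cfg@lambda * sum(vapply(SHu[jj], function(b) sum(abs(b)), numeric(1))) +
    cfg@gamma1 * vecNormL1(vectorField(gu@v1 - p@v1, gu@v2 - p@v2)) +
    cfg@gamma0 * tenNormL1(symGradient(p))
}

#' Solve the joint (u, p) subproblem of the ADMM splitting
#'
#' Given the current auxiliary variables and duals, approximately minimizes
#' the data fidelity plus the three quadratic coupling terms jointly over
#' (u, p). The pointwise nonlinearity is carried by the split t = Hu: each
#' sweep runs the damped-Newton prox of the convex scalar fidelity
#' \eqn{\phi(t) = \log t + f/t + \alpha(t/f-1)^2}, then solves the remaining
#' quadratic exactly through a per-frequency Hermitian 3 x 3 system, and
#' updates the internal multiplier; the sweep objective is monotone and the
#' iterates converge to the exact joint minimizer as sweeps grow.
#'
#' @param state an \linkS4class{ADMMState} (fields x/xd, y/yd, z/zd used as
#'   anchors; t/td as the fidelity split).
#' @param f observed image matrix, strictly positive, or NULL to disable the
#'   fidelity (pure quadratic subproblem).
#' @param psf \linkS4class{Psf} realizing H, or NULL for the identity.
#' @param cfg a \linkS4class{SolverConfig}.
#' @param system \linkS4class{ShearletSystem} matching \code{state};
#'   defaults to the cached system for the image shape.
#' @param sweeps number of (t, u, p) sweeps (default \code{cfg@innerSweeps}).
#' @param epsPosVal absolute positivity floor for t and u (defaults to the
#'   relative floor on a [0, 255] scale).
#' @return updated \linkS4class{ADMMState} (u, p, t, td refreshed).
#' @export
solveUpSubproblem <- function(state, f, psf = NULL, cfg = solverConfig(),
                              system = NULL, sweeps = cfg@innerSweeps,
                              epsPosVal = cfg@epsPosRel * 255) {
  m <- dim(state@u)
  if (is.null(system)) {
    system <- if (min(m) >= 32) buildShearletSystem(m[1], m[2], cfg@nScales)
              else trivialShearletSystem(m[1], m[2])
  }
  sym <- diffSymbols(m[1], m[2])
  Msym <- symGradNormalSymbols(sym)
  otf <- if (is.null(psf)) matrix(1 + 0i, m[1], m[2])
         else psf2otf(psf@kernel, m[1], m[2])
  eps <- epsPosVal
  hasFid <- !is.null(f)
  B <- upSystemInverse(if (hasFid) Mod(otf)^2 else matrix(0, m[1], m[2]),
                       sym, Msym, cfg)
  cx <- mapply(function(a, b) a - b, state@x, state@xd, SIMPLIFY = FALSE)
  Fx <- matrix(0i, m[1], m[2])
  for (j in seq_along(cx)) Fx <- Fx + system@filters[[j]] * fft2(cx[[j]])
  cy <- vectorField(state@y@v1 - state@yd@v1, state@y@v2 - state@yd@v2)
  cz <- symTensorField(state@z@w11 - state@zd@w11,
                       state@z@w12 - state@zd@w12,
                       state@z@w22 - state@zd@w22)
  u <- state@u; t <- state@t; td <- state@td
  for (s in seq_len(max(1L, sweeps))) {
    if (hasFid) {
      Hu <- ifft2Real(otf * fft2(u))
      t <- proxFidelity(Hu + td, f, cfg@alpha, cfg@mu0, eps, cfg@innerNewton)
    }
    r <- upRhs(Conj(otf), Fx, cy, cz,
               if (hasFid) t - td else matrix(0, m[1], m[2]), sym, cfg)
    sol <- applyUpInverse(B, r)
    u <- pmax(sol$u, eps)
    if (hasFid) {
      Hu <- ifft2Real(otf * fft2(u))
      td <- td + (Hu - t)
    }
  }
  state@u <- u
  state@p <- vectorField(sol$p1, sol$p2)
  state@t <- t
  state@td <- td
  state
}

#' Restore a single-channel image by ADMM
#'
#' Minimizes the TGV2 + shearlet restoration energy for an observed image f
#' degraded by multiplicative noise and (optionally) blur. The iteration is
#' carried out on the native [0, nMax] gray scale, starting from u = f; the
#' number of iterations is a genuine tuning parameter of the method (the
#' useful range is about 100-700): together with the shrinkage thresholds
#' it sets how much coefficient energy the l1 terms remove. The iteration
#' stops when the relative change of u falls below \code{cfg@tol} or after
#' \code{cfg@maxIter} iterations, and aborts with diagnostics if the energy
#' rises for 20 consecutive iterations. The restored image is returned
#' clipped to [0, nMax].
#'
#' @param f observed \linkS4class{ImageGrid} (single channel) or matrix,
#'   all pixels at or above the positivity floor.
#' @param psf the \linkS4class{Psf} realizing the blur (identity for pure
#'   denoising); its boundary rule must be periodic.
#' @param cfg a \linkS4class{SolverConfig}.
#' @return a \linkS4class{RestorationResult}.
#' @examples
#' u <- makeTestImage("phantom", n = 64)
#' d <- degradeImage(u, makePsf("identity"), noiseSpec("gamma", L = 10, seed = 1))
#' res <- admmRestore(d$image, makePsf("identity"),
#'                    solverConfig(lambda = 2, nScales = 2, maxIter = 30))
#' res
#' @export
admmRestore <- function(f, psf = makePsf("identity"), cfg = solverConfig()) {
  nMaxVal <- if (is(f, "ImageGrid")) nMax(f) else 255
  fmat <- if (is(f, "ImageGrid")) channelMatrix(f) else f
  if (psf@boundary != "periodic")
    stop("the solver requires a periodic-boundary Psf")
  eng <- admmEngineSingle(fmat, psf, cfg, nMaxVal = nMaxVal)
  new("RestorationResult",
      image = imageGrid(clamp(eng$u, 0, nMaxVal), nMax = nMaxVal),
      iterations = eng$iter, converged = eng$converged,
      history = eng$history, config = cfg)
}

## core single-channel engine on the native [0, nMax] gray scale ------------
admmEngineSingle <- function(fn, psf, cfg, nMaxVal = 255) {
  m <- dim(fn)
  eps <- cfg@epsPosRel * nMaxVal
  if (any(fn < eps)) fn <- pmax(fn, eps)
  sys <- if (min(m) >= 32) buildShearletSystem(m[1], m[2], cfg@nScales)
         else trivialShearletSystem(m[1], m[2])
  nb <- length(sys@filters)
  sym <- diffSymbols(m[1], m[2])
  Msym <- symGradNormalSymbols(sym)
  otf <- psf2otf(psf@kernel, m[1], m[2])
  otfc <- Conj(otf)
  B <- upSystemInverse(Mod(otf)^2, sym, Msym, cfg)
  zero <- matrix(0, m[1], m[2])

  ## initialization: u = f, p = 0, all splits/duals zero
  u <- fn
  p <- vectorField(zero, zero)
  x <- xd <- rep(list(zero), nb)
  y <- yd <- vectorField(zero, zero)
  z <- zd <- symTensorField(zero, zero, zero)
  t <- fn; td <- zero

  thrX <- cfg@lambda / cfg@mu1
  thrY <- cfg@gamma1 / cfg@mu2
  thrZ <- cfg@gamma0 / cfg@mu3
  hist <- vector("list", cfg@maxIter)
  res0 <- NULL
  badEnergy <- 0L
  lastE <- Inf
  convergedFlag <- FALSE
  it <- 0L

  repeat {
    it <- it + 1L
    uhat <- fft2(u)
    SHu <- shearletForwardSpec(uhat, sys)
    Hu <- ifft2Real(otf * uhat)
    gu <- imageGradient(u)
    ep <- symGradient(p)

    ## dual ascent for the previous primal updates (skipped at start where
    ## all variables are consistent zeros)
    if (it > 1L) {
      for (j in seq_len(nb)) xd[[j]] <- xd[[j]] + cfg@mu * (SHu[[j]] - x[[j]])
      y_res <- vectorField(gu@v1 - p@v1 - y@v1, gu@v2 - p@v2 - y@v2)
      yd <- vectorField(yd@v1 + cfg@mu * y_res@v1, yd@v2 + cfg@mu * y_res@v2)
      zd <- symTensorField(zd@w11 + cfg@mu * (ep@w11 - z@w11),
                           zd@w12 + cfg@mu * (ep@w12 - z@w12),
                           zd@w22 + cfg@mu * (ep@w22 - z@w22))
      td <- td + cfg@mu * (Hu - t)
    }

    ## primal residual norms of the constraint groups
    rx <- sqrt(sum(vapply(seq_len(nb),
                          function(j) sum((SHu[[j]] - x[[j]])^2), numeric(1))))
    ry <- sqrt(sum((gu@v1 - p@v1 - y@v1)^2 + (gu@v2 - p@v2 - y@v2)^2))
    rz <- sqrt(sum((ep@w11 - z@w11)^2 + 2 * (ep@w12 - z@w12)^2 +
                     (ep@w22 - z@w22)^2))

    ## shrinkage updates
    for (j in seq_len(nb)) {
      thr <- if (j == 1L && !cfg@penalizeLowpass) 0 else thrX
      x[[j]] <- shrink1(SHu[[j]] + xd[[j]], thr)
    }
    y <- shrink2(vectorField(gu@v1 - p@v1 + yd@v1, gu@v2 - p@v2 + yd@v2),
                 thrY)
    z <- shrinkF(symTensorField(ep@w11 + zd@w11, ep@w12 + zd@w12,
                                ep@w22 + zd@w22), thrZ)
    t <- proxFidelity(Hu + td, fn, cfg@alpha, cfg@mu0, eps, cfg@innerNewton)

    ## joint (u, p) solve: exact per-frequency Hermitian 3x3 system
    Fx <- matrix(0i, m[1], m[2])
    for (j in seq_len(nb)) Fx <- Fx + sys@filters[[j]] * fft2(x[[j]] - xd[[j]])
    cy <- vectorField(y@v1 - yd@v1, y@v2 - yd@v2)
    cz <- symTensorField(z@w11 - zd@w11, z@w12 - zd@w12, z@w22 - zd@w22)
    r <- upRhs(otfc, Fx, cy, cz, t - td, sym, cfg)
    sol <- applyUpInverse(B, r)
    uNew <- pmax(sol$u, eps)
    p <- vectorField(sol$p1, sol$p2)

    relChange <- sqrt(sum((uNew - u)^2)) / max(sqrt(sum(u^2)), 1e-12)
    E <- energyFromCache(Hu, fn, SHu, gu, p, ep, cfg, eps)
    hist[[it]] <- c(iter = it, energy = E, relChange = relChange,
                    resX = rx, resY = ry, resZ = rz)
    badEnergy <- if (E > lastE + 1e-6 * abs(lastE)) badEnergy + 1L else 0L
    lastE <- E
    u <- uNew
    if (badEnergy >= 20L) {
      h <- as.data.frame(do.call(rbind, hist[seq_len(it)]))
      cond <- structure(
        class = c("shearTGVDivergence", "error", "condition"),
        list(message = paste0("solver diverging: energy increased for 20 ",
                              "consecutive iterations (last energy ",
                              format(E), ")"),
             call = NULL, history = h))
      stop(cond)
    }
    if (relChange <= cfg@tol && it > 1L) { convergedFlag <- TRUE; break }
    if (it >= cfg@maxIter) break
  }

  list(u = u, iter = it, converged = convergedFlag,
       history = as.data.frame(do.call(rbind, hist[seq_len(it)])))
}
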