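#' @include solver.R
NULL

## inverse of a Hermitian positive-definite 3x3 system given entrywise
## matrices (vectorized over frequencies)
invHerm3 <- function(a11, a12, a13, a22, a23, a33) {
  a21 <- Conj(a12); a31 <- Conj(a13); a32 <- Conj(a23)
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

#' Restore a multichannel image with (possibly cross-channel) blur
#'
#' Minimizes the channel-summed restoration energy: the Gamma-MAP fidelity,
#' shearlet sparsity and TGV2 penalties act per channel, while the blur may
#' couple channels through an m x m kernel grid,
#' \eqn{(Hu)^{(k)} = \sum_l \omega_{kl} K_{kl} * u^{(l)}}. ADMM splits are
#' carried per channel; the coupled u-subproblem is solved exactly through a
#' per-frequency Hermitian m x m system, alternated with the per-channel
#' p-solves (\code{cfg@innerSweeps} sweeps).
#'
#' A single-channel input with a \linkS4class{Psf} reduces exactly to
#' \code{\link{admmRestore}}; a multichannel input with a plain
#' \linkS4class{Psf} (or a diagonal kernel grid) decouples into independent
#' channelwise restorations.
#'
#' @param f observed \linkS4class{ImageGrid} (1 or 3 channels).
#' @param blur a \linkS4class{Psf} (applied channelwise) or a
#'   \linkS4class{CrossChannelBlur} whose weight matrix matches the channel
#'   count.
#' @param cfg a \linkS4class{SolverConfig}.
#' @return a \linkS4class{RestorationResult}.
#' @export
restoreMultichannel <- function(f, blur = makePsf("identity"),
                                cfg = solverConfig()) {
  stopifnot(is(f, "ImageGrid"))
  nc <- nChannels(f)
  nMaxVal <- nMax(f)
  if (nc == 1L) {
    if (is(blur, "CrossChannelBlur"))
      stop("single-channel image cannot take a cross-channel blur")
    return(admmRestore(f, blur, cfg))
  }
  if (is(blur, "Psf")) {
    ## channelwise blur: the energy decouples; restore channels separately
    out <- array(0, dim(f@pixels))
    hs <- vector("list", nc); its <- integer(nc); conv <- logical(nc)
    for (k in seq_len(nc)) {
      r <- admmRestore(imageGrid(channelMatrix(f, k), nMax = nMaxVal),
                       blur, cfg)
      out[, , k] <- channelMatrix(restoredImage(r))
      hs[[k]] <- solverHistory(r); its[k] <- r@iterations
      conv[k] <- r@converged
    }
    h <- do.call(rbind, lapply(seq_len(nc), function(k)
      cbind(channel = k, hs[[k]])))
    return(new("RestorationResult",
               image = imageGrid(out, nMax = nMaxVal),
               iterations = max(its), converged = all(conv),
               history = h, config = cfg))
  }
  if (nrow(blur@weights) != nc)
    stop("blur couples ", nrow(blur@weights), " channels but the image has ",
         nc)
  if (nc != 3L)
    stop("cross-channel restoration is implemented for 3 channels (RGB)")
  eng <- admmEngineCoupled(f@pixels, blur, cfg, nMaxVal = nMaxVal)
  new("RestorationResult",
      image = imageGrid(clamp(eng$u, 0, nMaxVal), nMax = nMaxVal),
      iterations = eng$iter, converged = eng$converged,
      history = eng$history, config = cfg)
}

## coupled RGB engine on the native [0, nMax] gray scale ---------------------
admmEngineCoupled <- function(fn, blur, cfg, nMaxVal = 255) {
  d <- dim(fn); m <- d[1:2]; nc <- d[3]
  eps <- cfg@epsPosRel * nMaxVal
  fn <- pmax(fn, eps)
  sys <- if (min(m) >= 32) buildShearletSystem(m[1], m[2], cfg@nScales)
         else trivialShearletSystem(m[1], m[2])
  nb <- length(sys@filters)
  sym <- diffSymbols(m[1], m[2])
  Msym <- symGradNormalSymbols(sym)
  zero <- matrix(0, m[1], m[2])

  ## weighted transfer functions H_kl and the channel-coupled normal matrix
  Hf <- vector("list", nc * nc)
  for (k in seq_len(nc)) for (l in seq_len(nc)) {
    w <- blur@weights[k, l]
    Hf[[(k - 1) * nc + l]] <- if (w == 0) matrix(0i, m[1], m[2])
      else w * psf2otf(blur@kernels[[(k - 1) * nc + l]]@kernel, m[1], m[2])
  }
  HtH <- function(a, b) {
    acc <- matrix(0i, m[1], m[2])
    for (k in seq_len(nc))
      acc <- acc + Conj(Hf[[(k - 1) * nc + a]]) * Hf[[(k - 1) * nc + b]]
    acc
  }
  cdiag <- cfg@mu1 + cfg@mu2 * sym$lap
  Bu <- invHerm3(cfg@mu0 * HtH(1, 1) + cdiag,
                 cfg@mu0 * HtH(1, 2), cfg@mu0 * HtH(1, 3),
                 cfg@mu0 * HtH(2, 2) + cdiag,
                 cfg@mu0 * HtH(2, 3),
                 cfg@mu0 * HtH(3, 3) + cdiag)
  ## per-channel p-system inverse (Hermitian 2x2)
  P11 <- cfg@mu2 + cfg@mu3 * Msym$M11
  P22 <- cfg@mu2 + cfg@mu3 * Msym$M22
  P12 <- cfg@mu3 * Msym$M12
  Pdet <- Re(P11 * P22) - Mod(P12)^2

  applyH <- function(uhats, k) {
    acc <- matrix(0i, m[1], m[2])
    for (l in seq_len(nc)) acc <- acc + Hf[[(k - 1) * nc + l]] * uhats[[l]]
    ifft2Real(acc)
  }

  u <- lapply(seq_len(nc), function(k) fn[, , k])
  p <- rep(list(vectorField(zero, zero)), nc)
  x <- xd <- rep(list(rep(list(zero), nb)), nc)
  y <- yd <- rep(list(vectorField(zero, zero)), nc)
  z <- zd <- rep(list(symTensorField(zero, zero, zero)), nc)
  t <- u; td <- rep(list(zero), nc)

  thrX <- cfg@lambda / cfg@mu1
  thrY <- cfg@gamma1 / cfg@mu2
  thrZ <- cfg@gamma0 / cfg@mu3
  hist <- vector("list", cfg@maxIter)
  lastE <- Inf; badEnergy <- 0L; convergedFlag <- FALSE; it <- 0L

  repeat {
    it <- it + 1L
    uhats <- lapply(u, fft2)
    SHu <- lapply(uhats, shearletForwardSpec, system = sys)
    Hu <- lapply(seq_len(nc), function(k) applyH(uhats, k))
    gu <- lapply(u, imageGradient)
    epp <- lapply(p, symGradient)

    if (it > 1L) {
      for (k in seq_len(nc)) {
        for (j in seq_len(nb))
          xd[[k]][[j]] <- xd[[k]][[j]] + cfg@mu * (SHu[[k]][[j]] - x[[k]][[j]])
        yd[[k]] <- vectorField(
          yd[[k]]@v1 + cfg@mu * (gu[[k]]@v1 - p[[k]]@v1 - y[[k]]@v1),
          yd[[k]]@v2 + cfg@mu * (gu[[k]]@v2 - p[[k]]@v2 - y[[k]]@v2))
        zd[[k]] <- symTensorField(
          zd[[k]]@w11 + cfg@mu * (epp[[k]]@w11 - z[[k]]@w11),
          zd[[k]]@w12 + cfg@mu * (epp[[k]]@w12 - z[[k]]@w12),
          zd[[k]]@w22 + cfg@mu * (epp[[k]]@w22 - z[[k]]@w22))
        td[[k]] <- td[[k]] + cfg@mu * (Hu[[k]] - t[[k]])
      }
    }

    E <- 0
    for (k in seq_len(nc)) {
      thrs <- rep(thrX, nb)
      if (!cfg@penalizeLowpass) thrs[1L] <- 0
      for (j in seq_len(nb))
        x[[k]][[j]] <- shrink1(SHu[[k]][[j]] + xd[[k]][[j]], thrs[j])
      y[[k]] <- shrink2(vectorField(gu[[k]]@v1 - p[[k]]@v1 + yd[[k]]@v1,
                                    gu[[k]]@v2 - p[[k]]@v2 + yd[[k]]@v2),
                        thrY)
      z[[k]] <- shrinkF(symTensorField(epp[[k]]@w11 + zd[[k]]@w11,
                                       epp[[k]]@w12 + zd[[k]]@w12,
                                       epp[[k]]@w22 + zd[[k]]@w22), thrZ)
      t[[k]] <- proxFidelity(Hu[[k]] + td[[k]], fn[, , k], cfg@alpha,
                             cfg@mu0, eps, cfg@innerNewton)
      E <- E + energyFromCache(Hu[[k]], fn[, , k], SHu[[k]], gu[[k]],
                               p[[k]], epp[[k]], cfg, eps)
    }

    cy <- lapply(seq_len(nc), function(k)
      vectorField(y[[k]]@v1 - yd[[k]]@v1, y[[k]]@v2 - yd[[k]]@v2))
    cz <- lapply(seq_len(nc), function(k)
      symTensorField(z[[k]]@w11 - zd[[k]]@w11, z[[k]]@w12 - zd[[k]]@w12,
                     z[[k]]@w22 - zd[[k]]@w22))
    cthat <- lapply(seq_len(nc), function(k) fft2(t[[k]] - td[[k]]))
    Fx <- lapply(seq_len(nc), function(k) {
      acc <- matrix(0i, m[1], m[2])
      for (j in seq_len(nb))
        acc <- acc + sys@filters[[j]] * fft2(x[[k]][[j]] - xd[[k]][[j]])
      acc
    })

    uNew <- u
    for (s in seq_len(max(1L, cfg@innerSweeps))) {
      ## coupled u-solve given p
      rhs <- lapply(seq_len(nc), function(a) {
        acc <- cfg@mu1 * Fx[[a]]
        for (l in seq_len(nc))
          acc <- acc + cfg@mu0 * Conj(Hf[[(l - 1) * nc + a]]) * cthat[[l]]
        ph1 <- fft2(p[[a]]@v1 + cy[[a]]@v1)
        ph2 <- fft2(p[[a]]@v2 + cy[[a]]@v2)
        acc + cfg@mu2 * (Conj(sym$dxp) * ph1 + Conj(sym$dyp) * ph2)
      })
      uh1 <- Bu$B11 * rhs[[1]] + Bu$B12 * rhs[[2]] + Bu$B13 * rhs[[3]]
      uh2 <- Bu$B21 * rhs[[1]] + Bu$B22 * rhs[[2]] + Bu$B23 * rhs[[3]]
      uh3 <- Bu$B31 * rhs[[1]] + Bu$B32 * rhs[[2]] + Bu$B33 * rhs[[3]]
      uNew <- list(pmax(ifft2Real(uh1), eps), pmax(ifft2Real(uh2), eps),
                   pmax(ifft2Real(uh3), eps))
      ## per-channel p-solve given u
      for (k in seq_len(nc)) {
        gk <- imageGradient(uNew[[k]])
        d2 <- divergence2(cz[[k]])
        q1 <- fft2(cfg@mu2 * (gk@v1 - cy[[k]]@v1) - cfg@mu3 * d2@v1)
        q2 <- fft2(cfg@mu2 * (gk@v2 - cy[[k]]@v2) - cfg@mu3 * d2@v2)
        p[[k]] <- vectorField(ifft2Real((P22 * q1 - P12 * q2) / Pdet),
                              ifft2Real((P11 * q2 - Conj(P12) * q1) / Pdet))
      }
    }

    relChange <- sqrt(sum(vapply(seq_len(nc), function(k)
      sum((uNew[[k]] - u[[k]])^2), numeric(1)))) /
      max(sqrt(sum(vapply(u, function(a) sum(a^2), numeric(1)))), 1e-12)
    hist[[it]] <- c(iter = it, energy = E, relChange = relChange)
    badEnergy <- if (E > lastE + 1e-6 * abs(lastE)) badEnergy + 1L else 0L
    lastE <- E
    u <- uNew
    if (badEnergy >= 20L)
      stop("coupled solver diverging: energy increased for 20 consecutive ",
           "iterations")
    if (relChange <= cfg@tol && it > 1L) { convergedFlag <- TRUE; break }
    if (it >= cfg@maxIter) break
  }

  ua <- array(0, d)
  for (k in seq_len(nc)) ua[, , k] <- u[[k]]
  list(u = ua, iter = it, converged = convergedFlag,
       history = as.data.frame(do.call(rbind, hist[seq_len(it)])))
}
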