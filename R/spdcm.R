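#' Parameter index for a fully connected spectral DCM
#'
#' Defines the lossless bijection between the named model parameters and
#' the flat vector optimized by Variational Laplace: all n(n-1) directed
#' couplings, n log-scale self-connection deviations (the realized diagonal
#' is -0.5 exp(d), always negative), log-amplitude and exponent deviations
#' of the neuronal and observation noise spectra, and per-region transit
#' and decay log-deviations.
#'
#' @param regionNames character vector.
#' @return list(names, n, regionNames, type) where type tags each entry.
#' @export
dcmParamIndex <- function(regionNames) {
  n <- length(regionNames)
  a <- character(0)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i != j) a <- c(a, sprintf("a_%s_%s", regionNames[i], regionNames[j]))
  }
  nms <- c(a, paste0("self_", regionNames),
           "fluct_av", "fluct_bv", "fluct_ae", "fluct_be",
           paste0("transit_", regionNames), paste0("decay_", regionNames))
  type <- c(rep("a", length(a)), rep("self", n), rep("fluct", 4),
            rep("hemo", 2 * n))
  list(names = nms, n = n, regionNames = regionNames, type = type)
}

#' Shrinkage priors for spectral DCM inversion
#'
#' Off-diagonal couplings N(0, 1/64) Hz, self-connection log-deviations
#' N(0, 1/256), fluctuation and hemodynamic log-parameters N(0, 1/64).
#'
#' @param index from \code{dcmParamIndex()}.
#' @return list(mean, cov) with diagonal covariance.
#' @export
makeDcmPriors <- function(index) {
  v <- c(a = 1 / 64, self = 1 / 256, fluct = 1 / 64, hemo = 1 / 64)[index$type]
  list(mean = setNames(numeric(length(index$names)), index$names),
       cov = diag(unname(v), length(v)))
}

# Baseline constants about which the log-parameters deviate; these match
# the canonical generator defaults, and the power-law clamp below which
# the fluctuation spectra flatten.
.dcmBaseline <- function(n) {
  list(hemo = hemodynamicParams(n),
       alphaState0 = 0.001, betaState0 = 1, alphaObs0 = 1e-6, betaObs0 = 0,
       fmin = 0.008)
}

# Realize model matrices from the flat parameter vector.
.dcmRealize <- function(theta, index) {
  n <- index$n
  nA <- n * (n - 1)
  A <- matrix(0, n, n)
  k <- 0
  for (j in seq_len(n)) for (i in seq_len(n)) if (i != j) {
    k <- k + 1
    A[i, j] <- theta[k]
  }
  d <- theta[nA + seq_len(n)]
  diag(A) <- -0.5 * exp(d)
  fl <- theta[nA + n + 1:4]
  hemoDev <- theta[nA + n + 4 + seq_len(2 * n)]
  base <- .dcmBaseline(n)
  list(A = A,
       transit = base$hemo@transit * exp(hemoDev[seq_len(n)]),
       decay = base$hemo@decay * exp(hemoDev[n + seq_len(n)]),
       alphaState = base$alphaState0 * exp(fl[1]),
       betaState = base$betaState0 + fl[2],
       alphaObs = base$alphaObs0 * exp(fl[3]),
       betaObs = base$betaObs0 + fl[4],
       hemo = base$hemo)
}

# Fast path: predicted CSD array for a flat parameter vector.
.csdPredictTheta <- function(theta, index, freq) {
  m <- .dcmRealize(theta, index)
  h <- m$hemo
  csd_predict_cpp(freq, m$A, m$transit, m$decay, h@autoreg, h@stiffness,
                  h@oef, h@efficacy, h@V0, h@k1, h@k2, h@k3,
                  m$alphaState, m$betaState, m$alphaObs, m$betaObs,
                  fmin = .dcmBaseline(1)$fmin)
}

#' Predicted cross-spectral density of a parameterized DCM
#'
#' Evaluates \eqn{G_y(f) = H(f) G_v(f) H(f)^H + G_e(f)} with
#' \eqn{H(f) = B(f) (i 2 \pi f I - A)^{-1}}, where B(f) is the per-region
#' first-order hemodynamic transfer function obtained by linearizing the
#' balloon model about its fixed point, and G_v, G_e are diagonal power
#' laws. Errors if the realized coupling matrix is unstable.
#'
#' @param theta named flat parameter vector (see \code{dcmParamIndex}).
#' @param index parameter index.
#' @param freq frequency grid (Hz).
#' @return \linkS4class{CrossSpectra} with source "predicted".
#' @export
predictCsd <- function(theta, index, freq) {
  m <- .dcmRealize(theta, index)
  assertStable(m$A)
  new("CrossSpectra", freq = freq,
      csd = .csdPredictTheta(theta, index, freq),
      source = "predicted", regionNames = index$regionNames)
}

#' Estimate cross-spectra from ROI time series
#'
#' Fits a multivariate autoregressive model of the stated order by least
#' squares and evaluates the implied cross-spectral density on a fixed
#' frequency grid (default 32 points from 1/(N TR) to 0.25/TR). Spectral
#' features are evaluated on unfiltered (only demeaned) series. The
#' returned densities are two-sided, per Hz, Hermitian by construction.
#'
#' @param roi volumes x regions matrix.
#' @param TR sampling interval (s).
#' @param arOrder autoregressive order (default 8).
#' @param nFreq grid size.
#' @param freq optional explicit grid (Hz).
#' @return \linkS4class{CrossSpectra} with source "estimated".
#' @export
estimateCsd <- function(roi, TR, arOrder = 8, nFreq = 32, freq = NULL) {
  roi <- as.matrix(roi)
  nT <- nrow(roi)
  n <- ncol(roi)
  if (nT < 8 * arOrder) stop("need at least 8 x arOrder frames")
  roi <- sweep(roi, 2, colMeans(roi))
  if (is.null(freq))
    freq <- seq(1 / (nT * TR), 0.25 / TR, length.out = nFreq)
  rows <- seq.int(arOrder + 1, nT)
  Y <- roi[rows, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(arOrder),
                             function(k) roi[rows - k, , drop = FALSE]))
  XtX <- crossprod(X)
  B <- tryCatch(solve(XtX, crossprod(X, Y)), error = function(e) {
    warning("singular AR normal equations; applying ridge regularization")
    solve(XtX + diag(1e-6 * mean(diag(XtX)), ncol(X)), crossprod(X, Y))
  })
  E <- Y - X %*% B
  Sigma <- crossprod(E) / (nrow(Y) - ncol(X))
  csd <- array(complex(real = 0), c(n, n, length(freq)))
  rn <- colnames(roi)
  if (is.null(rn)) rn <- paste0("R", seq_len(n))
  for (k in seq_along(freq)) {
    Af <- diag(n) + 0i
    for (l in seq_len(arOrder)) {
      Al <- t(B[(l - 1) * n + seq_len(n), , drop = FALSE])
      Af <- Af - Al * exp(-2i * pi * freq[k] * l * TR)
    }
    Ainv <- solve(Af)
    S <- TR * Ainv %*% Sigma %*% Conj(t(Ainv))
    csd[, , k] <- (S + Conj(t(S))) / 2
  }
  new("CrossSpectra", freq = freq, csd = csd, source = "estimated",
      regionNames = rn)
}

#' Stack a cross-spectral array into a real observation vector
#'
#' Real and imaginary parts of the upper-triangular entries (diagonal real
#' parts included) stacked frequency by frequency. The companion band index
#' assigns each element to a noise precision group: contiguous frequency
#' bands, crossed with entry type (auto-spectra vs cross-spectra). The
#' split by entry type matters because auto-spectral densities are an
#' order of magnitude larger than cross terms; a shared precision would
#' let the fit ignore the cross-spectra, which carry the coupling
#' information.
#'
#' @param csd complex n x n x nfreq array.
#' @param nBands number of frequency bands (precision groups = 2 nBands).
#' @return list(y, band).
#' @export
vecCsd <- function(csd, nBands = 4) {
  d <- dim(csd)
  n <- d[1]
  ut <- which(upper.tri(matrix(0, n, n)))
  perFreq <- n + 2 * length(ut)
  y <- numeric(d[3] * perFreq)
  band <- integer(d[3] * perFreq)
  fb <- as.integer(cut(seq_len(d[3]), nBands, labels = FALSE))
  typ <- c(rep(0L, n), rep(1L, 2 * length(ut)))   # 0 = auto, 1 = cross
  for (k in seq_len(d[3])) {
    m <- csd[, , k]
    o <- (k - 1) * perFreq
    y[o + seq_len(perFreq)] <- c(Re(diag(m)), Re(m[ut]), Im(m[ut]))
    band[o + seq_len(perFreq)] <- (fb[k] - 1L) * 2L + typ + 1L
  }
  list(y = y, band = band)
}

#' Variational Laplace inversion of a nonlinear Gaussian model
#'
#' Maximizes the free energy F = accuracy - complexity under Gaussian
#' prior and posterior, with Gauss-Newton steps (finite-difference
#' Jacobian), Levenberg-style adaptive damping (a step is accepted only if
#' F increases), and noise log-precision hyperparameters per observation
#' band updated by Newton's method. Convergence is declared when the free
#' energy improves by less than \code{tol} for three consecutive accepted
#' iterations, or after \code{maxIter} iterations.
#'
#' @param predictor function(theta) -> predicted observation vector.
#' @param y observation vector.
#' @param priors list(mean, cov).
#' @param band integer vector assigning each observation to a precision
#'   band (default: a single band).
#' @param maxIter,tol iteration cap (64) and convergence threshold (0.01
#'   nats).
#' @param lambda0,lambdaVar hyperprior mean and variance of the log noise
#'   precisions; when \code{lambda0} is NULL (default) the hyperprior is
#'   centered per band on the log precision implied by the residual at the
#'   prior mean (a scale-free choice).
#' @param fixLambda optional fixed log precisions (length = number of
#'   bands); when given, no hyperparameter updates are performed (known
#'   noise).
#' @param step finite-difference step on the flat vector.
#' @param init optional starting point (defaults to the prior mean).
#' @return \linkS4class{DcmPosterior}.
#' @export
variationalLaplace <- function(predictor, y, priors, band = NULL,
                               maxIter = 64, tol = 0.01,
                               lambda0 = NULL, lambdaVar = 9,
                               fixLambda = NULL, step = 1e-4, init = NULL) {
  ny <- length(y)
  if (is.null(band)) band <- rep(1L, ny)
  nB <- max(band)
  p <- length(priors$mean)
  mu0 <- as.numeric(priors$mean)
  Sigma0 <- priors$cov
  Pi0 <- solve(Sigma0)
  ldS0 <- determinant(Sigma0, logarithm = TRUE)$modulus

  theta <- if (is.null(init)) mu0 else as.numeric(init)
  nBcount0 <- tabulate(band, nB)
  if (is.null(lambda0)) {
    # center the noise hyperprior at a precision corresponding to a small
    # fraction of the per-band data power (scale-free initialization)
    lambda0 <- vapply(seq_len(nB), function(b) {
      s2 <- 0.01 * sum(y[band == b]^2) / nBcount0[b]
      -log(max(s2, 1e-300))
    }, numeric(1))
  } else lambda0 <- rep_len(lambda0, nB)
  lam <- if (!is.null(fixLambda)) rep_len(fixLambda, nB) else lambda0
  estLambda <- is.null(fixLambda)

  jacobian <- function(th) {
    J <- matrix(0, ny, p)
    for (i in seq_len(p)) {
      tp <- th; tm <- th
      tp[i] <- tp[i] + step
      tm[i] <- tm[i] - step
      J[, i] <- (predictor(tp) - predictor(tm)) / (2 * step)
    }
    J
  }

  nBcount <- tabulate(band, nB)
  freeEnergy <- function(e, J, th, lam, SigmaP) {
    piv <- exp(lam)[band]
    dth <- th - mu0
    ldSp <- determinant(SigmaP, logarithm = TRUE)$modulus
    Fv <- -0.5 * sum(piv * e^2) + 0.5 * sum(nBcount * lam) -
      0.5 * ny * log(2 * pi) - 0.5 * sum(dth * (Pi0 %*% dth)) -
      0.5 * ldS0 + 0.5 * ldSp
    if (estLambda)
      Fv <- Fv - 0.5 * sum((lam - lambda0)^2) / lambdaVar
    as.numeric(Fv)
  }

  symSolve <- function(M) {
    M <- (M + t(M)) / 2
    out <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(out))
      out <- solve(M + diag(1e-10 * max(diag(M)), nrow(M)))
    out
  }

  updateLambda <- function(e, J, lam) {
    if (!estLambda) return(lam)
    for (it in 1:4) {
      piv <- exp(lam)[band]
      H <- crossprod(J, J * piv) + Pi0
      SigmaP <- symSolve(H)
      Js <- rowSums((J %*% SigmaP) * J)   # diag(J SigmaP J^T)
      for (b in seq_len(nB)) {
        sel <- band == b
        sb <- sum(e[sel]^2) + sum(Js[sel])
        g <- 0.5 * nBcount[b] - 0.5 * exp(lam[b]) * sb -
          (lam[b] - lambda0) / lambdaVar
        h <- -0.5 * exp(lam[b]) * sb - 1 / lambdaVar
        dl <- -g / h
        lam[b] <- lam[b] + max(min(dl, 4), -4)
      }
      # keep precisions within a broad but finite range of the hyperprior
      lam <- pmin(pmax(lam, lambda0 - 12), lambda0 + 12)
    }
    lam
  }

  evalState <- function(th, lam) {
    g <- predictor(th)
    if (any(!is.finite(g))) return(NULL)
    e <- y - g
    J <- jacobian(th)
    lam <- updateLambda(e, J, lam)
    piv <- exp(lam)[band]
    H <- crossprod(J, J * piv) + Pi0
    H <- (H + t(H)) / 2
    SigmaP <- symSolve(H)
    Fv <- freeEnergy(e, J, th, lam, SigmaP)
    list(e = e, J = J, lam = lam, H = H, SigmaP = SigmaP, F = Fv, theta = th)
  }

  st <- evalState(theta, lam)
  if (is.null(st) || !is.finite(st$F))
    stop("non-finite free energy at the prior mean; parameter snapshot: ",
         paste(signif(theta, 3), collapse = ", "))
  trace <- st$F
  nu <- 1e-8
  small <- 0
  iter <- 0
  while (iter < maxIter) {
    iter <- iter + 1
    piv <- exp(st$lam)[band]
    grad <- crossprod(st$J, piv * st$e) - Pi0 %*% (st$theta - mu0)
    accepted <- FALSE
    for (tryi in 1:12) {
      Hd <- st$H + nu * diag(diag(st$H), nrow(st$H))
      dtheta <- tryCatch(solve(Hd, grad), error = function(e2) NULL)
      if (!is.null(dtheta)) {
        cand <- evalState(st$theta + as.numeric(dtheta), st$lam)
        if (!is.null(cand) && is.finite(cand$F) && cand$F > st$F - 1e-12) {
          dF <- cand$F - st$F
          st <- cand
          trace <- c(trace, st$F)
          nu <- max(nu / 4, 1e-8)
          accepted <- TRUE
          small <- if (dF < tol) small + 1 else 0
          break
        }
      }
      nu <- min(nu * 16, 1e8)
    }
    if (!accepted) break
    if (small >= 3) break
  }
  new("DcmPosterior",
      mean = setNames(as.numeric(st$theta), names(priors$mean)),
      cov = st$SigmaP, freeEnergy = st$F, iterations = iter, trace = trace)
}

#' Invert one subject's fully connected spectral DCM
#'
#' Builds the full parameter index over all directed couplings and
#' self-connections, estimates the data cross-spectra by multivariate
#' autoregression, rescales them so the prior-mean predicted power matches
#' the data power (a global factor that leaves coupling estimates
#' invariant), and fits the generative model by Variational Laplace.
#'
#' @param roi volumes x regions matrix (column names = region names).
#' @param TR sampling interval (s).
#' @param arOrder,nFreq cross-spectral estimation settings.
#' @param nBands precision bands.
#' @param maxIter,tol Variational Laplace settings.
#' @return \linkS4class{DcmPosterior} with named parameters; the scale
#'   factor applied to the data spectra is stored in the trace attribute
#'   "csdScale".
#' @export
invertSubject <- function(roi, TR, arOrder = 8, nFreq = 32, nBands = 4,
                          maxIter = 64, tol = 0.01) {
  roi <- as.matrix(roi)
  if (ncol(roi) < 2) stop("need at least 2 ROIs")
  rn <- colnames(roi)
  if (is.null(rn)) rn <- paste0("R", seq_len(ncol(roi)))
  index <- dcmParamIndex(rn)
  priors <- makeDcmPriors(index)
  est <- estimateCsd(roi, TR, arOrder = arOrder, nFreq = nFreq)
  freq <- est@freq
  predMean <- .csdPredictTheta(priors$mean, index, freq)
  dPow <- mean(vapply(seq_along(freq),
                      function(k) mean(Re(diag(est@csd[, , k]))), numeric(1)))
  pPow <- mean(vapply(seq_along(freq),
                      function(k) mean(Re(diag(predMean[, , k]))), numeric(1)))
  scale <- pPow / dPow
  csd <- est@csd * scale
  obs <- vecCsd(csd, nBands = nBands)
  post <- variationalLaplace(
    function(th) vecCsd(.csdPredictTheta(th, index, freq), nBands)$y,
    obs$y, priors, band = obs$band, maxIter = maxIter, tol = tol)
  attr(post@trace, "csdScale") <- scale
  post
}

#' Extract the realized coupling matrix from a posterior
#'
#' @param post \linkS4class{DcmPosterior} from \code{invertSubject}.
#' @param regionNames region labels (recovered from parameter names when
#'   omitted).
#' @return \linkS4class{EffectiveConnectivity} at the posterior mean.
#' @export
posteriorA <- function(post, regionNames = NULL) {
  nms <- names(post@mean)
  if (is.null(regionNames))
    regionNames <- sub("^self_", "", grep("^self_", nms, value = TRUE))
  index <- dcmParamIndex(regionNames)
  m <- .dcmRealize(post@mean[index$names], index)
  effectiveConnectivity(m$A, regionNames)
}
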