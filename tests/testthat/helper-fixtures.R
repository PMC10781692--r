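# Shared fixture builders for the suite; everything is generated in code.

# Small stable coupling matrix with a couple of directed edges.
toyA <- function(n = 3, names = paste0("R", seq_len(n))) {
  A <- matrix(0, n, n, dimnames = list(names, names))
  diag(A) <- -0.5
  if (n >= 2) A[2, 1] <- 0.3
  if (n >= 3) A[3, 2] <- -0.25
  A
}

# Truth-valued flat parameter vector for a coupling matrix (other
# parameters at baseline).
thetaFromA <- function(A, index) {
  th <- setNames(numeric(length(index$names)), index$names)
  n <- nrow(A)
  k <- 0
  for (j in seq_len(n)) for (i in seq_len(n)) if (i != j) {
    k <- k + 1
    th[k] <- A[i, j]
  }
  th[k + seq_len(n)] <- log(diag(A) / -0.5)
  th
}

# Quick BOLD session from a coupling matrix under the generator defaults.
quickSession <- function(A, nVol = 350, TR = 2, seed = 1,
                         fluct = fluctuationSpec()) {
  tr <- simulateNeuronal(A, fluct, dt = 0.05, duration = nVol * TR,
                         seed = seed)
  y <- hemodynamicForward(tr, hemodynamicParams(ncol(A)), TR)
  set.seed(seed + 7)
  y <- y + powerLawNoise(nrow(y), TR, fluct@alphaObs, fluct@betaObs, ncol(y))
  colnames(y) <- rownames(A)
  y
}

# Tiny labelled volume: embed given ROI series into a block atlas.
quickVolume <- function(roi, gridShape = c(10, 10, 6), noiseSd = 0.005,
                        seed = 1) {
  labels <- makeAtlas(ncol(roi), gridShape)
  embedVolume(roi, labels, noiseSd = noiseSd, seed = seed)
}

# Synthetic first-level Gaussian posteriors around X %*% beta truth.
syntheticPosteriors <- function(X, betaTrue, paramNames, noiseSd = 0.05,
                                postSd = 0.03, seed = 1) {
  set.seed(seed)
  p <- length(paramNames)
  lapply(seq_len(nrow(X)), function(i) {
    mu <- as.numeric(matrix(betaTrue, p) %*% X[i, ]) +
      rnorm(p, 0, noiseSd)
    list(mean = setNames(mu + rnorm(p, 0, postSd), paramNames),
         cov = diag(postSd^2, p))
  })
}
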