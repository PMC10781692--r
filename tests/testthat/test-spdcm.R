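test_that("cross-spectral estimation matches closed forms", {
  set.seed(21)
  # independent white channels: low coherence (order matched to the
  # featureless truth)
  y <- matrix(rnorm(350 * 3), 350, 3)
  cs <- estimateCsd(y, TR = 2, arOrder = 2)
  coh <- sapply(seq_along(cs@freq), function(k) {
    m <- cs@csd[, , k]
    max(Mod(m[upper.tri(m)]) / sqrt(Re(diag(m))[col(m)[upper.tri(m)]] *
                                      Re(diag(m))[row(m)[upper.tri(m)]]))
  })
  expect_lt(max(coh), 0.2)

  # duplicated channel: coherence ~ 1 at all frequencies
  y2 <- cbind(y[, 1], y[, 1])
  expect_warning(cs2 <- estimateCsd(y2, TR = 2), "ridge")
  coh2 <- sapply(seq_along(cs2@freq), function(k) {
    m <- cs2@csd[, , k]
    Mod(m[1, 2]) / sqrt(Re(m[1, 1]) * Re(m[2, 2]))
  })
  expect_true(all(coh2 > 0.99))

  # univariate AR(1) spectrum: sigma^2 TR / |1 - a e^(-i omega)|^2
  a <- 0.7; TR <- 2
  set.seed(22)
  x <- as.numeric(arima.sim(list(ar = a), 20000))
  cs3 <- estimateCsd(matrix(x), TR = TR, arOrder = 4)
  theo <- TR / Mod(1 - a * exp(-2i * pi * cs3@freq * TR))^2
  expect_lt(mean(abs(Re(cs3@csd[1, 1, ]) - theo) / theo), 0.10)
})

test_that("predicted cross-spectra respect the generative structure", {
  idx <- dcmParamIndex(c("R1", "R2", "R3"))
  freq <- seq(0.01, 0.12, length.out = 16)
  th0 <- setNames(numeric(length(idx$names)), idx$names)
  # no couplings: off-diagonal cross-spectra exactly zero
  g0 <- predictCsd(th0, idx, freq)
  for (k in seq_along(freq)) {
    m <- g0@csd[, , k]
    expect_equal(max(Mod(m[upper.tri(m)])), 0)
  }
  # towering observation noise dominates the diagonal
  thN <- th0
  thN["fluct_ae"] <- 16
  gN <- predictCsd(thN, idx, freq)
  expect_gt(min(Re(gN@csd[1, 1, ]) / Re(g0@csd[1, 1, ])), 100)

  # Hermitian positive semidefinite at every frequency
  th <- thetaFromA(toyA(), idx)
  g <- predictCsd(th, idx, freq)
  for (k in seq_along(freq)) {
    m <- g@csd[, , k]
    expect_lt(max(Mod(m - Conj(t(m)))), 1e-12)
    expect_gt(min(eigen(m, only.values = TRUE)$values), -1e-10)
  }
  # unstable realized coupling matrix is refused
  thU <- th
  thU["a_R2_R1"] <- 2; thU["a_R1_R2"] <- 2
  expect_error(predictCsd(thU, idx, freq), "unstable")
})

test_that("simulated data agree with the model's predicted spectra", {
  A <- toyA()
  idx <- dcmParamIndex(rownames(A))
  y <- quickSession(A, nVol = 16384, TR = 0.5, seed = 23,
                    fluct = fluctuationSpec(alphaObs = 0))
  fr <- seq(0.01, 0.12, length.out = 24)
  est <- estimateCsd(y, TR = 0.5, freq = fr)
  pred <- predictCsd(thetaFromA(A, idx), idx, fr)
  de <- sapply(seq_along(fr), function(k) Re(diag(est@csd[, , k])))
  dp <- sapply(seq_along(fr), function(k) Re(diag(pred@csd[, , k])))
  # band-averaged relative error of the auto-spectral densities
  bands <- cut(seq_along(fr), 4, labels = FALSE)
  be <- sapply(1:4, function(b) rowMeans(de[, bands == b, drop = FALSE]))
  bp <- sapply(1:4, function(b) rowMeans(dp[, bands == b, drop = FALSE]))
  expect_lt(mean(abs(be - bp) / bp), 0.15)
})

test_that("Variational Laplace matches the conjugate Gaussian closed form", {
  set.seed(24)
  p <- 4; ny <- 40
  Xd <- matrix(rnorm(ny * p), ny, p)
  sig <- 0.3
  y <- as.numeric(Xd %*% rnorm(p)) + rnorm(ny, 0, sig)
  priors <- list(mean = setNames(rep(0, p), paste0("b", 1:p)),
                 cov = diag(0.5, p))
  post <- variationalLaplace(function(th) as.numeric(Xd %*% th), y, priors,
                             fixLambda = log(1 / sig^2))
  Sn <- solve(crossprod(Xd) / sig^2 + diag(2, p))
  mn <- as.numeric(Sn %*% crossprod(Xd, y) / sig^2)
  expect_lt(max(abs(post@mean - mn)), 1e-6)
  expect_lt(max(abs(post@cov - Sn)), 1e-6)
})

test_that("Variational Laplace is self-consistent and monotone in F", {
  idx <- dcmParamIndex(c("R1", "R2"))
  priors <- makeDcmPriors(idx)
  freq <- seq(0.01, 0.12, length.out = 16)
  pred <- function(th) vecCsd(specdcm:::.csdPredictTheta(th, idx, freq))$y
  yst <- vecCsd(specdcm:::.csdPredictTheta(priors$mean, idx, freq))
  # data generated at the prior mean with tiny noise: posterior stays there
  set.seed(25)
  yobs <- yst$y * (1 + rnorm(length(yst$y), 0, 1e-4))
  post <- variationalLaplace(pred, yobs, priors, band = yst$band)
  expect_lt(max(abs(post@mean - priors$mean)), 0.02)
  expect_true(all(diff(post@trace) >= -1e-9))
})

test_that("subject inversion indexes, labels and recovers couplings", {
  nm6 <- paste0("r", 1:6)
  idx6 <- dcmParamIndex(nm6)
  expect_equal(sum(idx6$type == "a"), 30)
  expect_equal(sum(idx6$type == "self"), 6)

  A <- toyA()
  A["R2", "R1"] <- 0.4
  y <- quickSession(A, nVol = 350, TR = 2, seed = 26)
  post <- invertSubject(y, TR = 2)
  est <- posteriorMean(post)[grep("^a_", names(posteriorMean(post)))]
  expect_equal(names(which.max(abs(est))), "a_R2_R1")
  expect_gt(est["a_R2_R1"], 0)
  # determinism: identical data give identical posteriors
  post2 <- invertSubject(y, TR = 2)
  expect_identical(posteriorMean(post), posteriorMean(post2))
  expect_error(invertSubject(y[, 1, drop = FALSE], TR = 2), "at least 2")
})

test_that("model evidence favors the true structure over wrong constraints", {
  A <- toyA()   # nonzero: a_R2_R1 = 0.3, a_R3_R2 = -0.25
  idx <- dcmParamIndex(rownames(A))
  priors <- makeDcmPriors(idx)
  wrong <- priors
  offIdx <- match(c("a_R2_R1", "a_R3_R2"), idx$names)
  diag(wrong$cov)[offIdx] <- 1e-8
  wins <- 0
  for (s in 1:10) {
    y <- quickSession(A, nVol = 350, TR = 2, seed = 300 + s)
    est <- estimateCsd(y, TR = 2)
    freq <- est@freq
    predMean <- specdcm:::.csdPredictTheta(priors$mean, idx, freq)
    dP <- mean(sapply(seq_along(freq), function(k)
      mean(Re(diag(est@csd[, , k])))))
    pP <- mean(sapply(seq_along(freq), function(k)
      mean(Re(diag(predMean[, , k])))))
    obs <- vecCsd(est@csd * pP / dP)
    predictor <- function(th)
      vecCsd(specdcm:::.csdPredictTheta(th, idx, freq))$y
    pFull <- variationalLaplace(predictor, obs$y, priors, band = obs$band)
    pWrong <- variationalLaplace(predictor, obs$y, wrong, band = obs$band)
    if (pFull@freeEnergy >= pWrong@freeEnergy) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
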