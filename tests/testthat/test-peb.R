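test_that("the group design encodes commonalities and centered contrasts", {
  tab <- data.frame(subject = rep(sprintf("s%02d", 1:26), each = 2),
                    session = rep(c("pre", "post"), 26),
                    responder_si = rep(c(TRUE, FALSE), 26)[1:52],
                    responder_dep = rep(rep(c(TRUE, FALSE), each = 2), 13))
  X <- buildDesign(tab)
  expect_equal(dim(X), c(52, 4))
  expect_equal(sum(X[, 1]), 52)
  expect_lt(max(abs(colMeans(X[, -1]))), 1e-12)
  expect_error(buildDesign(tab[, -2]), "missing design columns")
  # a contrast with no variation is flagged non-estimable
  tab2 <- tab; tab2$responder_si <- TRUE
  expect_warning(X2 <- buildDesign(tab2), "non-estimable")
  expect_true(all(X2[, "SIResponse"] == 0))
  expect_equal(attr(X2, "nonEstimable"), "SIResponse")
})

test_that("PEB estimation matches precision-weighted closed forms", {
  pn <- c("a1", "a2")
  priors <- list(mean = setNames(c(0, 0), pn), cov = diag(1 / 64, 2))
  gamma <- 2
  Qb <- diag(priors$cov) / 16 * exp(-gamma)

  # equal isotropic first-level covariances, ones-only design:
  # posterior = conjugate fusion of the subject means
  set.seed(31)
  mus <- lapply(1:8, function(i) rnorm(2, c(0.3, -0.1), 0.05))
  posts <- lapply(mus, function(m)
    list(mean = setNames(m, pn), cov = diag(0.04^2, 2)))
  X <- matrix(1, 8, 1, dimnames = list(NULL, "Commonalities"))
  peb <- pebFit(posts, X, paramNames = pn, priors = priors, gamma = gamma)
  Vi <- 0.04^2 + Qb[1]
  Pn <- 8 / Vi + 64
  expected <- (Reduce(`+`, mus) / Vi) / Pn
  expect_equal(peb@theta2Mean, expected, tolerance = 1e-8)
  expect_equal(diag(peb@theta2Cov), rep(1 / Pn, 2), tolerance = 1e-8,
               ignore_attr = TRUE)

  # heteroscedastic case: an imprecise subject barely moves the estimate
  posts2 <- posts
  posts2[[1]]$cov <- diag(0.4^2, 2)   # 100x larger covariance
  peb2 <- pebFit(posts2, X, paramNames = pn, priors = priors, gamma = gamma)
  V1 <- 0.4^2 + Qb[1]
  Pn2 <- 7 / Vi + 1 / V1 + 64
  expected2 <- (Reduce(`+`, mus[-1]) / Vi + mus[[1]] / V1) / Pn2
  expect_equal(peb2@theta2Mean, expected2, tolerance = 1e-8)

  # duplicating every subject shrinks the covariance, leaves the mean
  # (up to the weakened prior pull) in place
  pebD <- pebFit(c(posts, posts), rbind(X, X), paramNames = pn,
                 priors = priors, gamma = gamma)
  PnD <- 16 / Vi + 64
  expect_equal(pebD@theta2Mean, (2 * Reduce(`+`, mus) / Vi) / PnD,
               tolerance = 1e-8)
  expect_true(all(diag(pebD@theta2Cov) < diag(peb@theta2Cov)))
  expect_lt(max(abs(pebD@theta2Mean - peb@theta2Mean)), 0.01)

  # free energy is invariant to subject reordering
  ord <- c(5, 2, 8, 1, 7, 3, 6, 4)
  pebR <- pebFit(posts[ord], X, paramNames = pn, priors = priors)
  pebO <- pebFit(posts, X, paramNames = pn, priors = priors)
  expect_equal(pebR@freeEnergy, pebO@freeEnergy, tolerance = 1e-6)

  # misaligned parameter indices error
  postsBad <- posts
  names(postsBad[[3]]$mean) <- c("zz", "a2")
  expect_error(pebFit(postsBad, X, paramNames = pn, priors = priors),
               "misaligned")
})

test_that("Bayesian model reduction is exact and correctly signed", {
  set.seed(32)
  # identity reduction over random PSD inputs
  for (k in 1:20) {
    p <- sample(2:5, 1)
    L <- matrix(rnorm(p * p), p)
    S <- crossprod(L) + diag(0.1, p)
    Lp <- matrix(rnorm(p * p), p)
    Sp <- crossprod(Lp) + diag(0.1, p)
    post <- list(mean = rnorm(p), cov = S)
    pri <- list(mean = rnorm(p, 0, 0.1), cov = Sp)
    r <- bmr(post, pri, pri)
    expect_lt(abs(r$dF), 1e-10)
    expect_equal(r$mean, post$mean, tolerance = 1e-8, ignore_attr = TRUE)
  }

  # switching off a truly null parameter is rewarded most of the time,
  # switching off a strongly supported one is always punished
  priors <- list(mean = c(0, 0), cov = diag(1 / 64, 2))
  offFirst <- list(mean = c(0, 0),
                   cov = diag(c(1e-8, 1 / 64)))
  gains <- losses <- logical(100)
  set.seed(33)
  for (k in 1:100) {
    postNull <- list(mean = c(rnorm(1, 0, 0.02), 0.4), cov = diag(0.02^2, 2))
    postStrong <- list(mean = c(rnorm(1, 0.4, 0.02), 0), cov = diag(0.02^2, 2))
    gains[k] <- bmr(postNull, priors, offFirst)$dF > 0
    losses[k] <- bmr(postStrong, priors, offFirst)$dF < 0
  }
  expect_gte(mean(gains), 0.9)
  expect_true(all(losses))
})

test_that("greedy search prunes null effects and keeps planted ones", {
  pn <- paste0("c", 1:6)
  # strongly supported everywhere: search ends with the full model only
  postAll <- list(mean = setNames(rep(0.4, 6), pn), cov = diag(0.02^2, 6))
  pebLike <- new("PebModel", X = matrix(1, 4, 1), theta2Mean = postAll$mean,
                 theta2Cov = postAll$cov, eta = rep(0, 6),
                 priorCov = diag(1 / 64, 6), gamma = 0, freeEnergy = 0,
                 paramNames = pn)
  sr <- greedySearch(pebLike)
  expect_equal(nrow(sr$switches), 1)
  expect_true(all(sr$switches))

  # planted sparse truth: 2 of 12 group effects nonzero
  set.seed(34)
  pn12 <- paste0("g", 1:12)
  hits <- 0
  for (rep in 1:20) {
    truth <- rep(0, 12); truth[c(3, 9)] <- c(0.3, -0.25)
    est <- truth + rnorm(12, 0, 0.03)
    pebR <- new("PebModel", X = matrix(1, 4, 1),
                theta2Mean = est, theta2Cov = diag(0.03^2, 12),
                eta = rep(0, 12), priorCov = diag(1 / 64, 12), gamma = 0,
                freeEnergy = 0, paramNames = pn12)
    avg <- bma(greedySearch(pebR))
    if (all(posteriorProb(avg)[c(3, 9)] > 0.9) &&
        mean(posteriorProb(avg)[-c(3, 9)]) < 0.5) hits <- hits + 1
  }
  expect_gte(hits, 18)

  # deterministic given inputs
  sr2 <- greedySearch(pebLike)
  expect_identical(sr$F, sr2$F)
})

test_that("model averaging weights models by evidence", {
  pn <- c("p1", "p2")
  mkPost <- function(m) list(mean = setNames(m, pn), cov = diag(0.01, 2))
  sw <- rbind(c(TRUE, TRUE), c(TRUE, FALSE))
  colnames(sw) <- pn
  # single model: identity average
  one <- bma(list(switches = sw[1, , drop = FALSE], F = 0,
                  posteriors = list(mkPost(c(1, 2)))))
  expect_equal(posteriorMean(one), setNames(c(1, 2), pn))
  expect_equal(posteriorProb(one), setNames(c(1, 1), pn))

  # equal evidence: equal weights
  two <- bma(list(switches = sw, F = c(5, 5),
                  posteriors = list(mkPost(c(1, 2)), mkPost(c(3, 0)))))
  expect_equal(two@weights, c(0.5, 0.5))
  expect_equal(posteriorMean(two), setNames(c(2, 1), pn))
  expect_equal(posteriorProb(two)[["p2"]], 0.5)

  # a model 10 nats down contributes under 1e-4
  ten <- bma(list(switches = sw, F = c(10, 0),
                  posteriors = list(mkPost(c(1, 2)), mkPost(c(3, 0)))))
  expect_lt(ten@weights[2], 1e-4)
})
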