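test_that("neuronal simulation honors the stochastic differential equation", {
  # no driving input and zero initial state: identically zero trajectory
  tr0 <- simulateNeuronal(toyA(), fluctuationSpec(alphaState = 0),
                          dt = 0.05, duration = 50, seed = 1)
  expect_true(all(tr0@states == 0))

  # unstable matrix is rejected with the offending eigenvalues reported
  bad <- matrix(c(0.1, 0, 0, -0.5), 2, 2)
  expect_error(simulateNeuronal(bad, fluctuationSpec(), dt = 0.05,
                                duration = 10), "unstable")
  # integration step must resolve the fastest timescale
  fast <- diag(-40, 2)
  expect_error(simulateNeuronal(fast, fluctuationSpec(), dt = 0.05,
                                duration = 10), "too coarse")
})

test_that("stationary variance matches the Lyapunov solution for white noise", {
  # A = -0.5 I, white driving noise of density alpha: var = alpha / (2 * 0.5)
  A <- diag(-0.5, 2)
  alpha <- 0.02
  vs <- sapply(1:4, function(s) {
    tr <- simulateNeuronal(A, fluctuationSpec(alphaState = alpha,
                                              betaState = 0),
                           dt = 0.05, duration = 3000, seed = s)
    apply(tr@states, 2, var)
  })
  expect_equal(mean(vs), alpha / (2 * 0.5), tolerance = 0.05)
})

test_that("a directed coupling produces a lagged cross-correlation", {
  A <- matrix(c(-0.5, 0.3, 0, -0.5), 2, 2)  # region 1 -> region 2
  tr <- simulateNeuronal(A, fluctuationSpec(alphaState = 0.02,
                                            betaState = 0),
                         dt = 0.05, duration = 4000, seed = 3)
  cc <- ccf(tr@states[, 2], tr@states[, 1], lag.max = 100, plot = FALSE)
  peak <- cc$lag[which.max(cc$acf)]
  expect_gt(peak, 0)   # region 2 trails region 1
})

test_that("simulated spectra match the analytic transfer-function spectrum", {
  A <- toyA()
  alpha <- 0.001
  tr <- simulateNeuronal(A, fluctuationSpec(alphaState = alpha),
                         dt = 0.05, duration = 16384, seed = 7)
  # Bartlett-averaged two-sided periodogram
  n <- nrow(tr@states); L <- floor(n / 16)
  acc <- 0
  for (s in 1:16) {
    seg <- tr@states[((s - 1) * L + 1):(s * L), ]
    seg <- sweep(seg, 2, colMeans(seg))
    acc <- acc + Mod(mvfft(seg))^2 * tr@dt / L
  }
  pf <- (seq_len(L) - 1) / (L * tr@dt)
  sel <- which(pf > 0.01 & pf < 0.1)
  analytic <- sapply(pf[sel], function(f) {
    H <- solve(2i * pi * f * diag(3) - A)
    Re(diag((alpha / max(f, 0.008)) * H %*% Conj(t(H))))
  })
  ratio <- rowMeans(t((acc / 16)[sel, ]) / analytic)
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("balloon model has the right fixed point and impulse response", {
  h <- hemodynamicParams(2)
  y0 <- hemodynamicForward(new("LatentTrajectory", dt = 0.05,
                               states = matrix(0, 200, 2)), h, TR = 0.5)
  expect_equal(max(abs(y0)), 0)

  imp <- matrix(0, 400, 1)
  imp[21:25, 1] <- 1  # brief impulse at t = 1 s
  y <- hemodynamicForward(new("LatentTrajectory", dt = 0.05, states = imp),
                          hemodynamicParams(1), TR = 0.05)
  latency <- which.max(y[, 1]) * 0.05 - 1
  expect_gt(latency, 3)
  expect_lt(latency, 8)
  expect_lt(abs(y[nrow(y), 1]), 0.05 * max(y))  # returns to baseline

  # doubling the neuronal efficacy doubles the small-signal response
  small <- imp * 0.01
  tr <- new("LatentTrajectory", dt = 0.05, states = small)
  ya <- hemodynamicForward(tr, hemodynamicParams(1, efficacy = 0.4), 0.05)
  yb <- hemodynamicForward(tr, hemodynamicParams(1, efficacy = 0.8), 0.05)
  expect_equal(max(abs(yb)) / max(abs(ya)), 2, tolerance = 0.1)

  expect_error(hemodynamicParams(1, transit = -1), "positive")
})

test_that("volume embedding reproduces ROI series and isolates background", {
  set.seed(2)
  roi <- matrix(rnorm(350 * 3), 350, 3)
  labels <- makeAtlas(3, c(10, 10, 6))
  emb <- embedVolume(roi, labels, noiseSd = 0, seed = 1)
  for (r in 1:3)
    expect_equal(extractRoiSeries(emb$volume, labels == r), roi[, r])

  embN <- embedVolume(roi, labels, noiseSd = 1, seed = 5)
  bg <- which(as.vector(labels) == 0)[1:200]
  V <- matrix(embN$volume, prod(dim(labels)), 350)
  expect_lt(max(abs(colMeans(t(V[bg, ])))), 0.5)   # zero temporal mean
  rmax <- max(abs(cor(t(V[bg, ]), roi)))
  expect_lt(rmax, 0.3)

  # overlap detection and NIfTI round trip
  expect_error(makeAtlas(100, c(6, 6, 6)), "too small")
  tmp <- tempfile(fileext = ".nii.gz")
  writeVolumeNifti(emb$volume, tmp)
  back <- readVolumeNifti(tmp)
  expect_lt(max(abs(back - emb$volume)), 1e-6)
  expect_equal(attr(back, "affine"), emb$affine)
})

test_that("cohort generation is complete, deterministic and config-checked", {
  cfg <- cohortConfig(n_subjects = 26, n_volumes = 60,
                      region_names = c("DLPFC", "HIP", "INS"),
                      A_population = defaultPopulationA(c("DLPFC", "HIP", "INS")),
                      seed = 3)
  coh <- generateCohort(cfg)
  expect_length(subjects(coh), 26)
  for (s in subjects(coh)[1:3]) {
    expect_named(s@sessions, c("pre", "post"))
    expect_equal(nrow(s@sessions$pre$roi), 60)
  }
  # bit-identical regeneration from the same config
  coh2 <- generateCohort(cfg)
  expect_identical(subjects(coh)[[5]]@sessions$post$roi,
                   subjects(coh2)[[5]]@sessions$post$roi)
  expect_identical(clinicalScores(coh), clinicalScores(coh2))

  # stability guard on every generated coupling matrix
  eigs <- sapply(subjects(coh), function(s)
    max(Re(eigen(s@sessions$pre$A_true, only.values = TRUE)$values)))
  expect_true(all(eigs < 0))

  # clinical_effect referencing an absent connection errors
  expect_error(
    cohortConfig(region_names = c("A1", "B2"),
                 A_population = diag(-0.5, 2),
                 clinical_effect = list(scale = "BSI-CV", from = "HIP",
                                        to = "INS", slope = -1, intercept = 0.6,
                                        noise_sd = 0.1)),
    "absent")
})

test_that("degenerate clinical generation returns the deterministic map", {
  rn <- c("DLPFC", "HIP", "INS")
  cfg <- cohortConfig(n_subjects = 6, n_volumes = 60, region_names = rn,
                      A_population = defaultPopulationA(rn),
                      treatment_effect = matrix(0, 3, 3,
                                                dimnames = list(rn, rn)),
                      treatment_sd = 0,
                      clinical_effect = list(scale = "BSI-CV", from = "HIP",
                                             to = "INS", slope = -1.5,
                                             intercept = 0.65, noise_sd = 0),
                      seed = 8)
  coh <- generateCohort(cfg)
  clin <- clinicalScores(coh)
  bsi <- clin[clin$scale == "BSI-CV", ]
  for (sub in unique(bsi$subject)) {
    b <- bsi$value[bsi$subject == sub & bsi$timepoint == "baseline"]
    f <- bsi$value[bsi$subject == sub & bsi$timepoint == "post"]
    expect_equal(percentReduction(b, f), 0.65, tolerance = 1e-10)
  }
})

test_that("planted connectivity-outcome association is recoverable", {
  cfg <- cohortConfig(seed = 1)
  signs <- numeric(100)
  rs <- numeric(100)
  set.seed(41)
  for (k in 1:100) {
    shifts <- rnorm(26, -0.2, 0.1)
    clin <- plantClinicalScores(shifts, cfg)
    red <- attr(clin, "reduction")
    rs[k] <- cor(shifts, red)
    signs[k] <- rs[k] < 0
  }
  expect_gte(mean(signs), 0.95)
  expect_gte(mean(abs(rs)), 0.6)
})
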