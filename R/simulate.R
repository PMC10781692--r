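#' Construct an effective connectivity matrix
#'
#' @param values square numeric matrix of coupling rates (Hz); entry
#'   \code{[i, j]} is the influence of region j on region i.
#' @param regionNames optional labels (defaults to dimnames or R1..Rn).
#' @return an \linkS4class{EffectiveConnectivity}; errors if unstable.
#' @export
effectiveConnectivity <- function(values, regionNames = NULL) {
  if (is.null(regionNames))
    regionNames <- if (!is.null(rownames(values))) rownames(values) else
      paste0("R", seq_len(nrow(values)))
  new("EffectiveConnectivity", values = unname(as.matrix(values)),
      regionNames = regionNames)
}

#' @rdname effectiveConnectivity
#' @param object matrix or EffectiveConnectivity to check.
#' @export
assertStable <- function(object) {
  m <- if (is(object, "EffectiveConnectivity")) object@values else object
  ev <- eigen(m, only.values = TRUE)$values
  bad <- Re(ev) >= 0
  if (any(bad))
    stop("unstable coupling matrix; offending eigenvalues: ",
         paste(sprintf("%.4f%+.4fi", Re(ev[bad]), Im(ev[bad])), collapse = ", "))
  invisible(m)
}

#' Fluctuation and noise spectral specification
#'
#' @param alphaState,betaState neuronal fluctuation spectral density
#'   amplitude (units^2/Hz) and power-law exponent.
#' @param alphaObs,betaObs observation noise amplitude and exponent.
#' @export
fluctuationSpec <- function(alphaState = 0.001, betaState = 1,
                            alphaObs = 1e-6, betaObs = 0) {
  new("FluctuationSpec", alphaState = alphaState, betaState = betaState,
      alphaObs = alphaObs, betaObs = betaObs)
}

#' Balloon-Windkessel parameters
#'
#' Defaults are the widely used constants of the canonical hemodynamic
#' model: decay kappa = 0.64 1/s, autoregulation gamma = 0.32 1/s, transit
#' tau = 2 s, stiffness alpha = 0.32, resting O2 extraction rho = 0.4,
#' V0 = 0.04, with the classic BOLD coefficients k1 = 7 rho, k2 = 2,
#' k3 = 2 rho - 0.2.
#'
#' @param nRegions number of regions (scalars are recycled).
#' @param transit,decay,autoreg,stiffness,oef,efficacy,V0 model constants.
#' @export
hemodynamicParams <- function(nRegions = 1, transit = 2.0, decay = 0.64,
                              autoreg = 0.32, stiffness = 0.32, oef = 0.4,
                              efficacy = 0.4, V0 = 0.04) {
  new("HemodynamicParams",
      transit = rep_len(transit, nRegions), decay = rep_len(decay, nRegions),
      autoreg = autoreg, stiffness = stiffness, oef = oef, efficacy = efficacy,
      V0 = V0, k1 = 7 * oef, k2 = 2, k3 = 2 * oef - 0.2)
}

#' Gaussian noise with a power-law spectrum
#'
#' Generates noise with two-sided spectral density alpha * f^(-beta) by
#' spectral shaping of white noise on the simulation grid (the target
#' spectrum is exact on the grid). The power law is clamped (flattened)
#' below \code{fmin} so near-DC power stays finite: neuronal fluctuations
#' are band-limited, and drifts below the analysis band are the business
#' of detrending, not the dynamic model.
#'
#' @param n number of samples.
#' @param dt sampling interval (s).
#' @param alpha,beta spectral density amplitude and exponent.
#' @param nSeries number of independent series (columns).
#' @param fmin clamp frequency (Hz).
#' @return n x nSeries matrix.
#' @export
powerLawNoise <- function(n, dt, alpha, beta, nSeries = 1, fmin = 0.008) {
  if (alpha == 0) return(matrix(0, n, nSeries))
  w <- matrix(rnorm(n * nSeries, sd = sqrt(alpha / dt)), n, nSeries)
  if (beta == 0) return(w)
  f <- abs(seq(0, n - 1) / (n * dt))
  f[f > 1 / (2 * dt)] <- 1 / dt - f[f > 1 / (2 * dt)]   # fold to [-Nyq, Nyq]
  fmin <- max(fmin, 1 / (n * dt))
  g <- pmax(f, fmin)^(-beta / 2)
  g[1] <- 0                                             # remove DC
  Re(mvfft(mvfft(w) * g, inverse = TRUE)) / n
}

#' Simulate latent neuronal dynamics
#'
#' Integrates the linear stochastic differential equation
#' \eqn{\dot x(t) = A x(t) + v(t)} by Euler-Maruyama, where v(t) is
#' Gaussian noise with power-law spectrum \eqn{\alpha_s f^{-\beta_s}}.
#' A burn-in period is discarded so the returned trajectory is stationary.
#'
#' @param A \linkS4class{EffectiveConnectivity} or stable square matrix.
#' @param fluct \linkS4class{FluctuationSpec}.
#' @param dt integration step (s); must resolve the fastest timescale.
#' @param duration retained duration (s).
#' @param seed integer RNG seed.
#' @param burnin discarded initial period (s).
#' @return \linkS4class{LatentTrajectory} (duration/dt x n states).
#' @export
simulateNeuronal <- function(A, fluct, dt = 0.05, duration, seed = 1,
                             burnin = 60) {
  m <- assertStable(A)
  ev <- eigen(m, only.values = TRUE)$values
  tmin <- 1 / max(Mod(ev))
  if (dt > 0.1 * tmin)
    stop(sprintf("dt = %g too coarse for fastest timescale %.3g s", dt, tmin))
  n <- nrow(m)
  nKeep <- round(duration / dt)
  nTot <- nKeep + round(burnin / dt)
  set.seed(seed)
  v <- powerLawNoise(nTot, dt, fluct@alphaState, fluct@betaState, n)
  x <- numeric(n)
  M <- diag(n) + dt * m
  out <- matrix(0, nTot, n)
  for (t in seq_len(nTot)) {
    x <- M %*% x + dt * v[t, ]
    out[t, ] <- x
  }
  new("LatentTrajectory", dt = dt,
      states = out[(nTot - nKeep + 1):nTot, , drop = FALSE])
}

#' Hemodynamic (balloon-Windkessel) forward model
#'
#' Converts a latent neuronal trajectory into region-wise BOLD signal by
#' integrating the balloon model independently per region and sampling the
#' BOLD observation equation at the repetition time. The output is
#' fractional signal change about baseline (baseline = 0).
#'
#' @param traj \linkS4class{LatentTrajectory}.
#' @param h \linkS4class{HemodynamicParams} (per-region vectors recycled).
#' @param TR sampling interval (s); must be a multiple of the trajectory dt.
#' @return volumes x regions numeric matrix.
#' @export
hemodynamicForward <- function(traj, h, TR) {
  stopifnot(is(traj, "LatentTrajectory"), is(h, "HemodynamicParams"))
  dt <- traj@dt
  k <- TR / dt
  if (abs(k - round(k)) > 1e-8)
    stop("TR must be an integer multiple of the integration step dt")
  k <- round(k)
  X <- traj@states
  n <- ncol(X)
  hr <- new("HemodynamicParams", transit = rep_len(h@transit, n),
            decay = rep_len(h@decay, n), autoreg = h@autoreg,
            stiffness = h@stiffness, oef = h@oef, efficacy = h@efficacy,
            V0 = h@V0, k1 = h@k1, k2 = h@k2, k3 = h@k3)
  st <- list(s = numeric(n), f = rep(1, n), v = rep(1, n), q = rep(1, n))
  nVol <- floor(nrow(X) / k)
  y <- matrix(0, nVol, n)
  vol <- 0
  nStep <- nVol * k
  for (t in seq_len(nStep)) {
    # Heun (RK2) step; input held at x_t over the interval
    d1 <- .balloonDeriv(st, X[t, ], hr)
    pred <- list(s = st$s + dt * d1$s, f = st$f + dt * d1$f,
                 v = pmax(st$v + dt * d1$v, 1e-3),
                 q = pmax(st$q + dt * d1$q, 1e-3))
    d2 <- .balloonDeriv(pred, X[min(t + 1, nStep), ], hr)
    st <- list(s = st$s + dt / 2 * (d1$s + d2$s),
               f = st$f + dt / 2 * (d1$f + d2$f),
               v = pmax(st$v + dt / 2 * (d1$v + d2$v), 1e-3),
               q = pmax(st$q + dt / 2 * (d1$q + d2$q), 1e-3))
    if (t %% k == 0) {
      vol <- vol + 1
      y[vol, ] <- hr@V0 * (hr@k1 * (1 - st$q) + hr@k2 * (1 - st$q / st$v) +
                             hr@k3 * (1 - st$v))
    }
  }
  colnames(y) <- colnames(X)
  y
}

.balloonDeriv <- function(st, x, h) {
  E0 <- h@oef
  fi <- pmax(st$f, 1e-3)
  Ef <- 1 - (1 - E0)^(1 / fi)
  vv <- pmax(st$v, 1e-3)
  via <- vv^(1 / h@stiffness)
  list(s = h@efficacy * x - h@decay * st$s - h@autoreg * (st$f - 1),
       f = st$s,
       v = (st$f - via) / h@transit,
       q = (fi * Ef / E0 - via * st$q / vv) / h@transit)
}

#' Build a small block atlas
#'
#' Places each region as a cubic block of voxels inside a regular grid,
#' background label 0. Blocks are laid out on a coarse lattice; an error is
#' raised if regions would overlap (grid too small).
#'
#' @param nRegions number of regions.
#' @param gridShape integer triplet (each <= 32).
#' @param blockSize side length of each cubic region in voxels.
#' @return 3D integer array of labels.
#' @export
makeAtlas <- function(nRegions, gridShape = c(12, 12, 12), blockSize = 2) {
  stopifnot(all(gridShape <= 32), all(gridShape >= blockSize))
  lab <- array(0L, gridShape)
  perDim <- pmax(floor(gridShape / (blockSize + 1)), 1)
  if (prod(perDim) < nRegions) stop("grid too small for the requested regions")
  idx <- arrayInd(seq_len(nRegions), perDim)
  for (r in seq_len(nRegions)) {
    o <- (idx[r, ] - 1) * (blockSize + 1) + 1
    sel <- lab[o[1]:(o[1] + blockSize - 1), o[2]:(o[2] + blockSize - 1),
               o[3]:(o[3] + blockSize - 1)]
    if (any(sel != 0)) stop("overlapping atlas labels")
    lab[o[1]:(o[1] + blockSize - 1), o[2]:(o[2] + blockSize - 1),
        o[3]:(o[3] + blockSize - 1)] <- r
  }
  lab
}

#' Default affine for a synthetic grid
#'
#' Voxel indices (1-based) map to mm coordinates centered on the grid, so
#' roughly half of the first axis lies at negative x (left hemisphere in
#' the MNI convention used throughout).
#'
#' @param gridShape integer triplet.
#' @param voxelSize isotropic voxel size in mm.
#' @export
gridAffine <- function(gridShape, voxelSize = 6) {
  aff <- diag(c(rep(voxelSize, 3), 1))
  aff[1:3, 4] <- -voxelSize * (gridShape - 1) / 2 - voxelSize
  aff
}

#' Embed ROI time series into a labelled 4D volume
#'
#' Every voxel carrying a region's label receives that region's time series
#' plus i.i.d. Gaussian noise; background voxels receive noise only. The
#' label volume shares the grid and affine.
#'
#' @param roi volumes x regions matrix.
#' @param labels 3D integer label array (values 1..nRegions, 0 background),
#'   e.g. from \code{makeAtlas()}.
#' @param noiseSd voxelwise noise standard deviation.
#' @param seed RNG seed.
#' @param voxelSize isotropic voxel size (mm) used for the affine.
#' @return list with \code{volume} (4D array, attr "affine"), \code{labels}
#'   (3D array, attr "affine") and \code{affine}.
#' @export
embedVolume <- function(roi, labels, noiseSd = 0, seed = 1, voxelSize = 6) {
  nT <- nrow(roi)
  nReg <- ncol(roi)
  if (max(labels) > nReg) stop("labels reference more regions than provided")
  dims <- dim(labels)
  set.seed(seed)
  vol <- array(rnorm(prod(dims) * nT, sd = noiseSd), c(dims, nT))
  lin <- which(labels > 0)
  labv <- labels[lin]
  nVox <- prod(dims)
  for (r in seq_len(nReg)) {
    vox <- lin[labv == r]
    if (!length(vox)) next
    add <- rep(roi[, r], each = length(vox))
    idx <- rep(vox, nT) + nVox * rep(seq_len(nT) - 1L, each = length(vox))
    vol[idx] <- vol[idx] + add
  }
  aff <- gridAffine(dims, voxelSize)
  attr(vol, "affine") <- aff
  attr(labels, "affine") <- aff
  list(volume = vol, labels = labels, affine = aff)
}

#' Default population coupling matrix
#'
#' A sparse, stable directed network over the default five-region negative
#' connectivity model (stimulation target plus precuneus, hippocampus,
#' insula and sgACC): the target inhibits the precuneus and insula, the
#' insula excites the sgACC and hippocampus, and the hippocampus feeds back
#' to sgACC and insula. Self-connections sit at -0.5 Hz.
#'
#' @param regionNames character vector; couplings are planted where the
#'   canonical names are present, otherwise only self-connections.
#' @export
defaultPopulationA <- function(regionNames = c("DLPFC", "PCUN", "HIP",
                                               "INS", "sgACC")) {
  n <- length(regionNames)
  A <- matrix(0, n, n, dimnames = list(regionNames, regionNames))
  diag(A) <- -0.5
  setEdge <- function(from, to, w) {
    if (all(c(from, to) %in% regionNames)) A[to, from] <<- w
  }
  setEdge("DLPFC", "PCUN", -0.25)
  setEdge("DLPFC", "INS", -0.3)
  setEdge("INS", "sgACC", 0.3)
  setEdge("INS", "HIP", 0.25)
  setEdge("HIP", "sgACC", 0.2)
  setEdge("HIP", "INS", 0.25)
  setEdge("sgACC", "PCUN", -0.2)
  A
}

#' Cohort generator configuration
#'
#' Resolves and validates the configuration of the synthetic cohort: the
#' study conditions (26 subjects, two sessions, TR 2 s, 350 retained
#' volumes), the population coupling matrix and its between-subject
#' variability, the fluctuation and hemodynamic specifications, the
#' treatment effect applied to post-session couplings, and the linear map
#' from per-subject connection shifts to clinical score reductions.
#'
#' @param n_subjects,n_regions,TR,n_volumes cohort dimensions.
#' @param region_names region labels.
#' @param A_population population-mean coupling matrix.
#' @param A_sd between-subject s.d. of off-diagonal couplings (Hz).
#' @param self_sd between-subject s.d. of log self-connection deviations.
#' @param fluct \linkS4class{FluctuationSpec}.
#' @param hemo \linkS4class{HemodynamicParams}.
#' @param treatment_effect matrix of mean shifts added to the post-session
#'   coupling matrix (default: -0.2 Hz on the HIP -> INS connection).
#' @param treatment_sd between-subject s.d. of the shift on treated
#'   connections.
#' @param clinical_effect list(scale, from, to, slope, intercept, noise_sd):
#'   the planted linear map from a subject's realized shift on connection
#'   from -> to, to that subject's post-treatment percent reduction.
#' @param baseline_scores named list of c(mean, sd) per scale.
#' @param dt,burnin integration settings.
#' @param motion_sd random-walk step s.d. (mm / degrees) of synthetic
#'   motion tables.
#' @param n_motion_exceed number of subjects given a planted motion spike
#'   above the 3.5 mm exclusion limit.
#' @param volumes logical; also embed ROI series into 4D volumes.
#' @param grid_shape,voxel_size,embed_noise_sd volume embedding settings.
#' @param seed integer seed recorded in all outputs.
#' @return a validated list of class "cohort_config".
#' @export
cohortConfig <- function(n_subjects = 26,
                         region_names = c("DLPFC", "PCUN", "HIP", "INS", "sgACC"),
                         n_regions = length(region_names),
                         TR = 2, n_volumes = 350,
                         A_population = defaultPopulationA(region_names),
                         A_sd = 0.05, self_sd = 0.05,
                         fluct = fluctuationSpec(),
                         hemo = hemodynamicParams(n_regions),
                         treatment_effect = NULL,
                         treatment_sd = 0.1,
                         clinical_effect = list(scale = "BSI-CV", from = "HIP",
                                                to = "INS", slope = -1.5,
                                                intercept = 0.65,
                                                noise_sd = 0.1),
                         baseline_scores = list(
                           "BSI-CV" = c(17.6, 7.1), "HAMD-17" = c(27.9, 4.3),
                           "HAMD-6" = c(13.6, 2.2), "MADRS" = c(36.7, 4.5),
                           "BDI" = c(35.8, 9.2)),
                         dt = 0.05, burnin = 60,
                         motion_sd = 0.02, n_motion_exceed = 0,
                         volumes = FALSE, grid_shape = c(12, 12, 12),
                         voxel_size = 6, embed_noise_sd = 0.005,
                         seed = 1) {
  if (n_volumes < 50) stop("n_volumes must be >= 50")
  if (TR <= 0) stop("TR must be positive")
  if (length(region_names) != n_regions) stop("region_names length mismatch")
  if (is.null(treatment_effect)) {
    treatment_effect <- matrix(0, n_regions, n_regions,
                               dimnames = list(region_names, region_names))
    if (all(c("HIP", "INS") %in% region_names))
      treatment_effect["INS", "HIP"] <- -0.2
  }
  if (!is.null(clinical_effect)) {
    if (!all(c(clinical_effect$from, clinical_effect$to) %in% region_names))
      stop("clinical_effect references a connection absent from the model: ",
           clinical_effect$from, " -> ", clinical_effect$to)
  }
  cfg <- list(n_subjects = n_subjects, n_regions = n_regions,
              region_names = region_names, TR = TR, n_volumes = n_volumes,
              A_population = A_population, A_sd = A_sd, self_sd = self_sd,
              fluct = fluct, hemo = hemo,
              treatment_effect = treatment_effect, treatment_sd = treatment_sd,
              clinical_effect = clinical_effect,
              baseline_scores = baseline_scores,
              dt = dt, burnin = burnin, motion_sd = motion_sd,
              n_motion_exceed = n_motion_exceed, volumes = volumes,
              grid_shape = grid_shape, voxel_size = voxel_size,
              embed_noise_sd = embed_noise_sd, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Draw a stable per-subject coupling matrix around the population mean.
# The stability guard enforces a margin, not just Re(eig) < 0: network
# modes slower than ~1/margin seconds are barely sampled in a 12-minute
# session and make the inverse problem ill-conditioned, which a cohort
# designed for connectivity analysis would avoid.
.drawSubjectA <- function(cfg, margin = 0.2) {
  n <- cfg$n_regions
  for (try in 1:200) {
    A <- cfg$A_population
    off <- !diag(n)
    A[off] <- A[off] + rnorm(sum(off), sd = cfg$A_sd)
    diag(A) <- -0.5 * exp(rnorm(n, sd = cfg$self_sd))
    if (max(Re(eigen(A, only.values = TRUE)$values)) < -margin) return(A)
  }
  stop("failed to draw a stable subject coupling matrix")
}

#' Plant clinical scores from connection shifts
#'
#' Generates longitudinal clinical scores for a cohort given each subject's
#' realized treatment shift on the clinically coupled connection. The
#' post-treatment percent reduction on the targeted scale is
#' \code{intercept + slope * shift + noise}; remaining scales and later
#' timepoints improve progressively with independent noise. Scores are
#' clipped at zero.
#'
#' @param shifts numeric vector: per-subject realized shift (Hz) on the
#'   clinical-effect connection.
#' @param cfg a \code{cohortConfig()}.
#' @return list of per-subject long data.frames (scale, timepoint, value)
#'   with attribute "reduction" holding the planted post reductions.
#' @export
plantClinicalScores <- function(shifts, cfg) {
  ce <- cfg$clinical_effect
  n <- length(shifts)
  tps <- c("baseline", "post", "week2", "week4")
  later <- c(post = 0.55, week2 = 0.65, week4 = 0.75)
  out <- vector("list", n)
  planted <- numeric(n)
  for (i in seq_len(n)) {
    rows <- list()
    for (sc in names(cfg$baseline_scores)) {
      bs <- cfg$baseline_scores[[sc]]
      base <- max(rnorm(1, bs[1], bs[2]), 1)
      red <- pmin(pmax(rnorm(3, later, 0.15), -0.2), 1)
      if (!is.null(ce) && sc == ce$scale) {
        red[1] <- min(max(ce$intercept + ce$slope * shifts[i] +
                            rnorm(1, 0, ce$noise_sd), -0.2), 1)
        planted[i] <- red[1]
      }
      vals <- c(base, base * (1 - red))
      rows[[sc]] <- data.frame(scale = sc, timepoint = tps,
                               value = pmax(vals, 0))
    }
    out[[i]] <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  attr(out, "reduction") <- planted
  out
}

#' Generate a synthetic cohort
#'
#' Draws per-subject coupling matrices around the population mean, applies
#' the treatment effect to the post session, simulates neuronal dynamics
#' and hemodynamics for both sessions, synthesizes motion tables and
#' clinical scores with the planted connectivity-outcome association, and
#' (optionally) embeds the ROI series into labelled 4D volumes. Fully
#' reproducible from the seed in the configuration.
#'
#' @param cfg a \code{cohortConfig()}.
#' @return a \linkS4class{Cohort}.
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  subSeeds <- matrix(sample.int(1000000000L, 3 * n), n, 3)
  treated <- which(cfg$treatment_effect != 0)
  shifts <- numeric(n)
  ceIdx <- NA_integer_
  if (!is.null(cfg$clinical_effect)) {
    ceIdx <- (match(cfg$clinical_effect$from, cfg$region_names) - 1) *
      cfg$n_regions + match(cfg$clinical_effect$to, cfg$region_names)
  }
  As <- vector("list", n)
  shiftMats <- vector("list", n)
  for (i in seq_len(n)) {
    As[[i]] <- .drawSubjectA(cfg)
    sm <- matrix(0, cfg$n_regions, cfg$n_regions)
    sm[treated] <- cfg$treatment_effect[treated] +
      rnorm(length(treated), sd = cfg$treatment_sd)
    shiftMats[[i]] <- sm
    shifts[i] <- if (!is.na(ceIdx)) sm[ceIdx] else 0
  }
  clin <- plantClinicalScores(shifts, cfg)
  labels <- if (cfg$volumes)
    makeAtlas(cfg$n_regions, cfg$grid_shape) else NULL
  exceedSubjects <- if (cfg$n_motion_exceed > 0)
    sample(n, cfg$n_motion_exceed) else integer(0)

  duration <- cfg$n_volumes * cfg$TR
  makeSession <- function(A, seed, spike) {
    for (try in 0:99) {
      traj <- simulateNeuronal(A, cfg$fluct, dt = cfg$dt, duration = duration,
                               seed = seed + try, burnin = cfg$burnin)
      y <- hemodynamicForward(traj, cfg$hemo, cfg$TR)
      if (all(is.finite(y))) break
    }
    set.seed(seed + 500)
    y <- y + powerLawNoise(nrow(y), cfg$TR, cfg$fluct@alphaObs,
                           cfg$fluct@betaObs, ncol(y))
    colnames(y) <- cfg$region_names
    motion <- apply(matrix(rnorm(nrow(y) * 6, sd = cfg$motion_sd),
                           nrow(y), 6), 2, cumsum)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    if (spike) motion[sample(nrow(motion), 1), 1] <- 4.2
    sess <- list(roi = y, volume = NULL, motion = motion, A_true = A)
    if (cfg$volumes)
      sess$volume <- embedVolume(y, labels, cfg$embed_noise_sd,
                                 seed = seed + 900, cfg$voxel_size)$volume
    sess
  }

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    Apre <- As[[i]]
    Apost <- Apre + shiftMats[[i]]
    if (any(Re(eigen(Apost, only.values = TRUE)$values) >= 0))
      Apost <- Apre   # degenerate draw: keep the stable pre matrix
    spike <- i %in% exceedSubjects
    recs[[i]] <- new("SubjectRecord",
                     subjectId = sprintf("sub-%02d", i),
                     sessions = list(
                       pre = makeSession(Apre, subSeeds[i, 1], spike),
                       post = makeSession(Apost, subSeeds[i, 2], FALSE)),
                     clinical = clin[[i]],
                     target = numeric(0))
  }
  cohort <- new("Cohort", subjects = recs, config = unclass(cfg))
  cohort@config$labels <- labels
  cohort
}
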