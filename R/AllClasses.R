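#' @import methods
NULL

.isSquare <- function(m) is.matrix(m) && nrow(m) == ncol(m)

#' Directed coupling matrix of a linear neuronal network
#'
#' The central estimand of the pipeline: an n x n matrix of first-order
#' coupling rates (Hz). Entry \code{[i, j]} is the directed influence of
#' region j on region i; the diagonal holds the (negative) self-connections
#' that confer stability. Validity requires every eigenvalue of the realized
#' matrix to have strictly negative real part, so that the stochastic
#' differential equation \eqn{\dot x = A x + v} has a stationary solution.
#'
#' @slot values numeric matrix of coupling rates (Hz).
#' @slot regionNames character vector of region labels, one per row/column.
#' @export
setClass("EffectiveConnectivity",
  representation(values = "matrix", regionNames = "character"),
  validity = function(object) {
    v <- object@values
    if (!.isSquare(v)) return("coupling matrix must be square")
    if (!all(is.finite(v))) return("coupling matrix must be finite")
    if (length(object@regionNames) != nrow(v))
      return("regionNames length must equal matrix dimension")
    ev <- Re(eigen(v, only.values = TRUE)$values)
    if (any(ev >= 0))
      return(sprintf(
        "unstable coupling matrix: eigenvalue real parts not all negative (max %.4f)",
        max(ev)))
    TRUE
  })

#' Spectral profile of endogenous fluctuations and observation noise
#'
#' Both the neuronal driving fluctuations and the measurement noise are
#' modelled as stationary processes with power-law spectral densities
#' \eqn{G(f) = \alpha f^{-\beta}}. Amplitudes are two-sided spectral
#' densities (signal units squared per Hz); exponents are restricted to
#' \code{[0, 2]} (white through near-Brownian).
#'
#' @slot alphaState,betaState amplitude and exponent of the neuronal
#'   fluctuation spectrum.
#' @slot alphaObs,betaObs amplitude and exponent of the observation-noise
#'   spectrum.
#' @export
setClass("FluctuationSpec",
  representation(alphaState = "numeric", betaState = "numeric",
                 alphaObs = "numeric", betaObs = "numeric"),
  validity = function(object) {
    a <- c(object@alphaState, object@alphaObs)
    b <- c(object@betaState, object@betaObs)
    if (any(a < 0)) return("amplitudes must be non-negative")
    if (any(b < 0 | b > 2)) return("spectral exponents must lie in [0, 2]")
    TRUE
  })

#' Balloon-Windkessel hemodynamic parameters
#'
#' Region-wise biophysical constants of the hemodynamic model that maps
#' neuronal activity to BOLD: transit time tau (s), vasodilatory signal decay
#' kappa (1/s), flow autoregulation gamma (1/s), vessel stiffness alpha,
#' resting oxygen extraction rho, neurovascular efficacy epsilon, and the
#' BOLD observation coefficients V0, k1, k2, k3.
#'
#' @slot transit,decay per-region vectors (recycled from scalars).
#' @slot autoreg,stiffness,oef,efficacy,V0,k1,k2,k3 scalar constants.
#' @export
setClass("HemodynamicParams",
  representation(transit = "numeric", decay = "numeric", autoreg = "numeric",
                 stiffness = "numeric", oef = "numeric", efficacy = "numeric",
                 V0 = "numeric", k1 = "numeric", k2 = "numeric", k3 = "numeric"),
  validity = function(object) {
    pos <- c(object@transit, object@decay, object@autoreg, object@stiffness,
             object@oef, object@efficacy, object@V0)
    if (any(pos <= 0)) return("hemodynamic parameters must be strictly positive")
    if (any(object@stiffness > 1)) return("stiffness alpha must lie in (0, 1]")
    if (any(object@oef >= 1)) return("resting O2 extraction must lie in (0, 1)")
    TRUE
  })

#' Latent neuronal state trajectory
#'
#' @slot dt time step (s).
#' @slot states T x n matrix of hidden neuronal states on the uniform grid.
#' @export
setClass("LatentTrajectory",
  representation(dt = "numeric", states = "matrix"),
  validity = function(object) {
    if (object@dt <= 0) return("dt must be positive")
    if (!all(is.finite(object@states))) return("states must be finite")
    TRUE
  })

#' Complex cross-spectral density over a frequency grid
#'
#' The data feature fitted by spectral DCM: an n x n Hermitian matrix of
#' two-sided cross-spectral densities at each frequency. Densities are in
#' signal units squared per Hz.
#'
#' @slot freq ascending frequency grid (Hz), strictly positive.
#' @slot csd complex array n x n x nfreq.
#' @slot source either "estimated" (from data) or "predicted" (from a model).
#' @slot regionNames character labels.
#' @export
setClass("CrossSpectra",
  representation(freq = "numeric", csd = "array", source = "character",
                 regionNames = "character"),
  validity = function(object) {
    d <- dim(object@csd)
    if (length(d) != 3 || d[1] != d[2]) return("csd must be n x n x nfreq")
    if (d[3] != length(object@freq)) return("frequency grid does not match csd")
    if (any(object@freq <= 0) || is.unsorted(object@freq))
      return("freq must be positive and ascending")
    if (!object@source %in% c("estimated", "predicted"))
      return("source must be 'estimated' or 'predicted'")
    for (k in seq_len(d[3])) {
      m <- object@csd[, , k]
      if (max(Mod(m - Conj(t(m)))) > 1e-10 * max(1, max(Mod(m))))
        return(sprintf("csd not Hermitian at frequency index %d", k))
      if (any(Re(diag(m)) < -1e-12))
        return("diagonal spectral densities must be non-negative")
    }
    TRUE
  })

#' Gaussian parameter posterior with free energy
#'
#' The unit of information passed from first-level (subject) inversion to
#' second-level (group) inference: a multivariate Gaussian over the flat
#' parameter vector together with the variational free energy (an evidence
#' lower bound, in nats) and a convergence record.
#'
#' @slot mean named numeric vector of posterior expectations.
#' @slot cov posterior covariance matrix.
#' @slot freeEnergy scalar free energy (nats).
#' @slot iterations number of Variational Laplace iterations run.
#' @slot trace free energy after each accepted step.
#' @export
setClass("DcmPosterior",
  representation(mean = "numeric", cov = "matrix", freeEnergy = "numeric",
                 iterations = "numeric", trace = "numeric"),
  validity = function(object) {
    p <- length(object@mean)
    if (!all(dim(object@cov) == c(p, p))) return("cov dimension mismatch")
    if (max(abs(object@cov - t(object@cov))) > 1e-8 * max(1, max(abs(object@cov))))
      return("posterior covariance must be symmetric")
    if (!is.finite(object@freeEnergy)) return("free energy must be finite")
    TRUE
  })

#' Second-level parametric empirical Bayes model
#'
#' Hierarchical GLM over first-level posteriors: each subject/session
#' parameter vector is modelled as X beta plus random between-subject
#' effects, and beta (the group-level parameters, one block per design
#' column) carries its own Gaussian prior. The first design column is the
#' commonalities (group mean) column; subsequent columns are zero-centered
#' contrasts.
#'
#' @slot X design matrix (rows = first-level posteriors).
#' @slot theta2Mean,theta2Cov posterior of the group parameters (stacked
#'   connection-by-covariate, covariate blocks in column order).
#' @slot eta,priorCov prior mean and covariance of the group parameters.
#' @slot gamma log precision scale of the between-subject random effects.
#' @slot freeEnergy scalar model evidence bound (nats).
#' @slot paramNames names of the group parameters.
#' @export
setClass("PebModel",
  representation(X = "matrix", theta2Mean = "numeric", theta2Cov = "matrix",
                 eta = "numeric", priorCov = "matrix", gamma = "numeric",
                 freeEnergy = "numeric", paramNames = "character"),
  validity = function(object) {
    if (!all(object@X[, 1] == 1)) return("first design column must be all ones")
    if (ncol(object@X) > 1) {
      cm <- colMeans(object@X[, -1, drop = FALSE])
      if (any(abs(cm) > 1e-8)) return("contrast columns must be zero-centered")
    }
    p <- length(object@theta2Mean)
    if (!all(dim(object@theta2Cov) == c(p, p))) return("theta2Cov mismatch")
    TRUE
  })

#' Bayesian model average over reduced models
#'
#' @slot mean,variance moment-matched averaged posterior per parameter.
#' @slot pp posterior probability that each parameter is switched on.
#' @slot weights model weights (non-negative, summing to one).
#' @slot switches logical matrix, models x parameters.
#' @export
setClass("BmaResult",
  representation(mean = "numeric", variance = "numeric", pp = "numeric",
                 weights = "numeric", switches = "matrix"),
  validity = function(object) {
    if (any(object@weights < -1e-12)) return("weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to one")
    if (any(object@pp < -1e-12 | object@pp > 1 + 1e-12))
      return("posterior probabilities must lie in [0, 1]")
    TRUE
  })

#' One subject of a cohort
#'
#' Container mirroring the study layout: two resting-state sessions (pre and
#' post treatment), each with ROI time series, an optional 4D volume, a
#' motion table and the ground-truth coupling matrix (when synthetic), plus
#' longitudinal clinical scores and the individualized stimulation target.
#'
#' @slot subjectId character id.
#' @slot sessions named list ("pre", "post"); each element a list with
#'   \code{roi}, \code{volume} (or NULL), \code{motion}, \code{A_true}.
#' @slot clinical long-format data.frame: scale, timepoint, value.
#' @slot target numeric MNI mm triplet (or length 0 before selection).
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", sessions = "list",
                 clinical = "data.frame", target = "numeric"),
  validity = function(object) {
    if (!all(c("pre", "post") %in% names(object@sessions)))
      return("sessions must contain 'pre' and 'post'")
    rn <- lapply(object@sessions, function(s) colnames(s$roi))
    if (!identical(rn$pre, rn$post))
      return("pre and post sessions must share region ordering")
    if (nrow(object@clinical)) {
      neg <- object@clinical$scale %in% c("BSI-CV", "HAMD-17") &
        object@clinical$value < 0
      if (any(neg, na.rm = TRUE)) return("BSI-CV/HAMD-17 scores must be >= 0")
    }
    TRUE
  })

#' A synthetic cohort with its generating configuration
#'
#' @slot subjects list of \linkS4class{SubjectRecord}.
#' @slot config the resolved \code{cohortConfig()} list (seed included).
#' @export
setClass("Cohort",
  representation(subjects = "list", config = "list"),
  validity = function(object) {
    if (!all(vapply(object@subjects, is, TRUE, "SubjectRecord")))
      return("subjects must all be SubjectRecord")
    if (is.null(object@config$seed)) return("config must record the seed")
    TRUE
  })
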