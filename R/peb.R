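#' Second-level design matrix
#'
#' Four columns: a constant (commonalities), session coded -0.5 (pre) /
#' +0.5 (post), and effect-coded, mean-centered responder contrasts for
#' suicidal ideation and depression. Contrast columns are exactly
#' zero-centered; a contrast with no variation (all subjects responders,
#' or none) is all zeros after centering and flagged non-estimable.
#'
#' @param subjectTable data.frame with one row per first-level posterior:
#'   columns \code{subject}, \code{session} ("pre"/"post"),
#'   \code{responder_si}, \code{responder_dep} (logical).
#' @return design matrix with attribute "nonEstimable".
#' @export
buildDesign <- function(subjectTable) {
  need <- c("subject", "session", "responder_si", "responder_dep")
  miss <- setdiff(need, names(subjectTable))
  if (length(miss)) stop("missing design columns: ", paste(miss, collapse = ", "))
  if (any(is.na(subjectTable$responder_si)) ||
      any(is.na(subjectTable$responder_dep)))
    stop("missing responder flags")
  sess <- ifelse(subjectTable$session == "post", 0.5, -0.5)
  code <- function(flag) {
    x <- ifelse(flag, 0.5, -0.5)
    x - mean(x)
  }
  X <- cbind(Commonalities = 1, Session = sess - mean(sess),
             SIResponse = code(subjectTable$responder_si),
             DepResponse = code(subjectTable$responder_dep))
  nonEst <- colnames(X)[-1][apply(X[, -1, drop = FALSE], 2,
                                  function(c) all(abs(c) < 1e-12))]
  if (length(nonEst))
    warning("non-estimable design column(s): ", paste(nonEst, collapse = ", "))
  attr(X, "nonEstimable") <- nonEst
  X
}

# Extract aligned mean vectors / covariance blocks for a parameter subset.
.alignPosteriors <- function(posteriors, paramNames) {
  mus <- lapply(posteriors, function(p) {
    m <- if (is(p, "DcmPosterior")) p@mean else p$mean
    if (!all(paramNames %in% names(m)))
      stop("posterior parameter indices are misaligned")
    m[paramNames]
  })
  covs <- lapply(posteriors, function(p) {
    S <- if (is(p, "DcmPosterior")) p@cov else p$cov
    nm <- if (is(p, "DcmPosterior")) names(p@mean) else names(p$mean)
    idx <- match(paramNames, nm)
    S[idx, idx, drop = FALSE]
  })
  list(mu = mus, cov = covs)
}

#' Fit a parametric empirical Bayes model over subject posteriors
#'
#' Hierarchical Gaussian model: each first-level posterior enters as a
#' likelihood with its own covariance; first-level parameters are modelled
#' as X beta plus random between-subject effects with covariance
#' exp(-gamma) * diag(priorCov)/16; beta carries a Gaussian prior (the
#' first-level prior for the commonalities block, zero for contrasts).
#' For fixed gamma the beta posterior is available in closed form; gamma
#' is estimated by maximizing the (marginal) free energy.
#'
#' @param posteriors list of \linkS4class{DcmPosterior} (or lists with
#'   \code{mean}, \code{cov}) sharing a parameter index.
#' @param X design matrix, rows aligned with posteriors.
#' @param paramNames subset of first-level parameters to model (default:
#'   couplings and self-connections).
#' @param priors first-level priors for the subset (list mean, cov);
#'   reconstructed from the parameter names when omitted.
#' @param gamma optional fixed log precision scale of the between-subject
#'   effects; estimated when NULL.
#' @return \linkS4class{PebModel}.
#' @export
pebFit <- function(posteriors, X, paramNames = NULL, priors = NULL,
                   gamma = NULL) {
  if (length(posteriors) != nrow(X))
    stop("rows of X must align with posteriors")
  nm1 <- if (is(posteriors[[1]], "DcmPosterior")) names(posteriors[[1]]@mean)
         else names(posteriors[[1]]$mean)
  if (is.null(paramNames))
    paramNames <- grep("^(a|self)_", nm1, value = TRUE)
  if (!length(paramNames)) stop("empty parameter subset")
  al <- .alignPosteriors(posteriors, paramNames)
  p <- length(paramNames)
  N <- length(posteriors)
  q <- ncol(X)
  if (is.null(priors)) {
    rn <- sub("^self_", "", grep("^self_", nm1, value = TRUE))
    full <- makeDcmPriors(dcmParamIndex(rn))
    idx <- match(paramNames, names(full$mean))
    priors <- list(mean = full$mean[idx], cov = full$cov[idx, idx, drop = FALSE])
  }
  S0d <- diag(as.matrix(priors$cov))
  eta <- c(as.numeric(priors$mean), rep(0, p * (q - 1)))
  SigmaBeta <- diag(rep(S0d, q), p * q)
  PiBeta <- diag(1 / rep(S0d, q), p * q)
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("X", seq_len(q))
  pname <- as.vector(vapply(cn, function(cc) paste0(cc, ":", paramNames),
                            character(p)))
  muAll <- unlist(al$mu, use.names = FALSE)
  W <- kronecker(X, diag(p))

  Qb <- S0d / 16
  objective <- function(g) {
    Vi <- lapply(al$cov, function(S) S + diag(exp(-g) * Qb, p))
    # integrate beta analytically: y ~ N(W eta, V + W SigmaBeta W')
    C <- matrix(0, N * p, N * p)
    for (i in seq_len(N)) {
      ii <- (i - 1) * p + seq_len(p)
      C[ii, ii] <- Vi[[i]]
    }
    C <- C + W %*% SigmaBeta %*% t(W)
    r <- muAll - W %*% eta
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    ld <- 2 * sum(log(diag(ch)))
    quad <- sum(backsolve(ch, r, transpose = TRUE)^2)
    -0.5 * (ld + quad + N * p * log(2 * pi)) - 0.5 * g^2 * 16
  }
  if (is.null(gamma)) {
    opt <- optimize(objective, c(-5, 5), maximum = TRUE, tol = 1e-4)
    gamma <- opt$maximum
    Fval <- opt$objective
  } else {
    Fval <- objective(gamma)
  }
  Vi <- lapply(al$cov, function(S) S + diag(exp(-gamma) * Qb, p))
  ViInv <- lapply(Vi, solve)
  Pi <- PiBeta
  rhs <- PiBeta %*% eta
  for (i in seq_len(N)) {
    Wi <- kronecker(matrix(X[i, ], 1), diag(p))   # p x pq
    Pi <- Pi + t(Wi) %*% ViInv[[i]] %*% Wi
    rhs <- rhs + t(Wi) %*% ViInv[[i]] %*% al$mu[[i]]
  }
  Pi <- (Pi + t(Pi)) / 2
  SigmaPost <- solve(Pi)
  muPost <- as.numeric(SigmaPost %*% rhs)
  new("PebModel", X = X, theta2Mean = muPost,
      theta2Cov = (SigmaPost + t(SigmaPost)) / 2,
      eta = eta, priorCov = SigmaBeta, gamma = gamma,
      freeEnergy = as.numeric(Fval), paramNames = pname)
}

#' Bayesian model reduction
#'
#' Analytic evidence and posterior of a model whose priors have been
#' tightened, computed from the full model's Gaussian posterior and prior
#' without refitting. Near-singular precision combinations fall back to a
#' pseudo-inverse with a logged condition number.
#'
#' @param posterior list(mean, cov) (or \linkS4class{DcmPosterior}).
#' @param priorsFull,priorsReduced lists (mean, cov); the reduced prior
#'   covariance must not exceed the full one parameter-wise.
#' @return list(dF = F_reduced - F_full, mean, cov).
#' @export
bmr <- function(posterior, priorsFull, priorsReduced) {
  mu <- if (is(posterior, "DcmPosterior")) posterior@mean else posterior$mean
  S <- if (is(posterior, "DcmPosterior")) posterior@cov else posterior$cov
  mu0 <- as.numeric(priorsFull$mean);  S0 <- as.matrix(priorsFull$cov)
  mur <- as.numeric(priorsReduced$mean); Sr <- as.matrix(priorsReduced$cov)
  if (any(diag(Sr) > diag(S0) + 1e-12))
    stop("reduced prior covariance exceeds the full prior")
  inv <- function(M) {
    out <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(out)) {
      kap <- kappa(M)
      warning(sprintf("singular precision combination (condition %.3g); %s",
                      kap, "using pseudo-inverse"))
      ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
      keep <- abs(ev$values) > max(abs(ev$values)) * 1e-12
      out <- ev$vectors[, keep] %*% (t(ev$vectors[, keep]) / ev$values[keep])
    }
    out
  }
  P <- inv(S); P0 <- inv(S0); Pr <- inv(Sr)
  Pnew <- P + Pr - P0
  Snew <- inv((Pnew + t(Pnew)) / 2)
  munew <- as.numeric(Snew %*% (P %*% mu + Pr %*% mur - P0 %*% mu0))
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  dF <- 0.5 * (ld(Pr) - ld(P0) + ld(P) - ld(Pnew)) -
    0.5 * (sum(mur * (Pr %*% mur)) - sum(mu0 * (P0 %*% mu0)) +
             sum(mu * (P %*% mu)) - sum(munew * (Pnew %*% munew)))
  list(dF = as.numeric(dF), mean = setNames(munew, names(mu)),
       cov = (Snew + t(Snew)) / 2)
}

# Reduced prior with selected parameters switched off (variance collapsed).
.reducedPriors <- function(priors, off, offVar = 1e-8) {
  pr <- list(mean = priors$mean, cov = as.matrix(priors$cov))
  if (any(off)) {
    pr$mean[off] <- 0
    pr$cov[off, ] <- 0
    pr$cov[, off] <- 0
    diag(pr$cov)[off] <- offVar
  }
  pr
}

#' Greedy search over reduced second-level models
#'
#' Iterative pruning of group-level parameters: at each pass every
#' currently-on parameter is evaluated for switching off via Bayesian
#' model reduction, all prunings that increase model evidence are applied,
#' and the search stops when none improve (or after 8 passes). The final
#' step enumerates the on/off combinations of the remaining least certain
#' parameters (capped at 2^8 models) and returns the model set with
#' evidences and reduced posteriors.
#'
#' @param peb \linkS4class{PebModel}.
#' @param searchIdx indices (or names) of group parameters eligible for
#'   pruning; all by default.
#' @param maxPass pass cap.
#' @param capK neighborhood size cap (2^capK models).
#' @return list(switches, F, posteriors, priorsFull); F is relative to the
#'   full model.
#' @export
greedySearch <- function(peb, searchIdx = NULL, maxPass = 8, capK = 8) {
  post <- list(mean = setNames(peb@theta2Mean, peb@paramNames),
               cov = peb@theta2Cov)
  priors <- list(mean = setNames(peb@eta, peb@paramNames), cov = peb@priorCov)
  p <- length(post$mean)
  if (is.null(searchIdx)) searchIdx <- seq_len(p)
  if (is.character(searchIdx)) searchIdx <- match(searchIdx, peb@paramNames)
  on <- rep(TRUE, p)
  evalOff <- function(off) bmr(post, priors, .reducedPriors(priors, off))
  lastDF <- rep(NA_real_, p)
  for (pass in seq_len(maxPass)) {
    cand <- intersect(searchIdx, which(on))
    if (!length(cand)) break
    base <- evalOff(!on)$dF
    dFs <- vapply(cand, function(i) {
      off <- !on; off[i] <- TRUE
      evalOff(off)$dF - base      # evidence change relative to current model
    }, numeric(1))
    lastDF[cand] <- dFs
    prune <- cand[dFs > 0]
    if (!length(prune)) break
    on[prune] <- FALSE
  }
  # terminal neighborhood: enumerate on/off combinations of the parameters
  # whose retention is not decisive (pruning would cost < 3 nats), capped
  uncertain <- intersect(searchIdx, which(on & !is.na(lastDF) & lastDF > -3))
  if (length(uncertain) > capK) {
    ord <- order(abs(lastDF[uncertain]))
    uncertain <- uncertain[ord[seq_len(capK)]]
  }
  k <- length(uncertain)
  combos <- if (k > 0) {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  } else matrix(FALSE, 1, 0)
  nm <- nrow(combos)
  switches <- matrix(TRUE, nm, p, dimnames = list(NULL, peb@paramNames))
  switches[, !on] <- FALSE
  Fs <- numeric(nm)
  posts <- vector("list", nm)
  for (m in seq_len(nm)) {
    off <- !on
    if (k > 0) off[uncertain] <- combos[m, ]
    switches[m, ] <- !off
    red <- evalOff(off)
    Fs[m] <- red$dF
    posts[[m]] <- red[c("mean", "cov")]
  }
  list(switches = switches, F = Fs, posteriors = posts, priorsFull = priors)
}

#' Bayesian model averaging
#'
#' Evidence-weighted, moment-matched Gaussian average over a set of
#' (reduced) models; the per-parameter posterior probability is the summed
#' weight of models in which that parameter is switched on.
#'
#' @param search result of \code{greedySearch} (or a compatible list with
#'   switches, F, posteriors).
#' @return \linkS4class{BmaResult}.
#' @export
bma <- function(search) {
  Fs <- search$F
  if (!length(Fs)) stop("no models to average")
  if (any(!is.finite(Fs))) stop("non-finite model evidences")
  w <- exp(Fs - max(Fs))
  w <- w / sum(w)
  p <- ncol(search$switches)
  nms <- colnames(search$switches)
  mu <- numeric(p); m2 <- numeric(p)
  for (m in seq_along(w)) {
    pm <- as.numeric(search$posteriors[[m]]$mean)
    pv <- diag(as.matrix(search$posteriors[[m]]$cov))
    mu <- mu + w[m] * pm
    m2 <- m2 + w[m] * (pv + pm^2)
  }
  vv <- pmax(m2 - mu^2, 0)
  pp <- as.numeric(w %*% search$switches)
  new("BmaResult", mean = setNames(mu, nms), variance = setNames(vv, nms),
      pp = setNames(pmin(pmax(pp, 0), 1), nms), weights = w,
      switches = search$switches)
}
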