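#' Discard initial volumes
#'
#' Removes the first k frames from a time series matrix or 4D volume (and,
#' when supplied, from the paired motion table in lockstep), emulating the
#' removal of pre-steady-state scans.
#'
#' @param x volumes x regions matrix, or 4D array (time last).
#' @param k number of initial frames to drop.
#' @param motion optional motion table trimmed alongside.
#' @return trimmed x, or list(data, motion) when motion is given.
#' @export
discardInitial <- function(x, k, motion = NULL) {
  nT <- if (is.matrix(x) || is.data.frame(x)) nrow(x) else dim(x)[4]
  if (k >= nT) stop(sprintf("cannot discard %d of %d frames", k, nT))
  out <- if (is.matrix(x) || is.data.frame(x)) {
    x[seq.int(k + 1, nT), , drop = FALSE]
  } else {
    a <- attr(x, "affine")
    y <- x[, , , seq.int(k + 1, nT), drop = FALSE]
    attr(y, "affine") <- a
    y
  }
  if (is.null(motion)) return(out)
  if (nrow(motion) != nT) stop("motion table length does not match data")
  list(data = out, motion = motion[seq.int(k + 1, nT), , drop = FALSE])
}

#' Motion-based exclusion rule
#'
#' A session is dropped iff any absolute translation exceeds the limit in
#' mm or any absolute rotation exceeds the limit in degrees. The rule is a
#' strict inequality ("larger than"), so values exactly at the limit are
#' retained.
#'
#' @param motion volumes x 6 table: three translations (mm) then three
#'   rotations (degrees).
#' @param transLimit,rotLimit exclusion limits (default 3.5 mm / 3.5 deg).
#' @return list(keep, maxTranslation, maxRotation, offending).
#' @export
motionExclusion <- function(motion, transLimit = 3.5, rotLimit = 3.5) {
  stopifnot(transLimit > 0, rotLimit > 0, ncol(motion) >= 6)
  m <- as.matrix(motion)[, 1:6, drop = FALSE]
  mt <- max(abs(m[, 1:3]))
  mr <- max(abs(m[, 4:6]))
  keep <- !(mt > transLimit || mr > rotLimit)
  off <- numeric(0)
  if (!keep) {
    off <- c(if (mt > transLimit) c(translation = mt),
             if (mr > rotLimit) c(rotation = mr))
  }
  list(keep = keep, maxTranslation = mt, maxRotation = mr, offending = off)
}

#' Friston 24-parameter motion expansion
#'
#' The six realignment parameters, their one-volume-lagged copies (first
#' row zero-padded), and the squares of both sets, in that column order.
#'
#' @param motion volumes x 6 motion table.
#' @return volumes x 24 matrix with stable column names.
#' @export
friston24 <- function(motion) {
  m <- as.matrix(motion)
  if (ncol(m) < 6) stop("motion table must have 6 columns")
  if (nrow(m) < 2) stop("need at least 2 volumes")
  m <- m[, 1:6, drop = FALSE]
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  lag <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, lag, m^2, lag^2)
  colnames(out) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
                     paste0(base, "_lag_sq"))
  out
}

#' Remove linear trend
#'
#' @param series volumes x k matrix.
#' @return detrended series (intercept and linear slope removed).
#' @export
detrendSeries <- function(series) {
  series <- as.matrix(series)
  t <- seq_len(nrow(series))
  X <- cbind(1, t - mean(t))
  series - X %*% qr.coef(qr(X), series)
}

#' Regress confounds out of a time series
#'
#' Ordinary-least-squares residualization against an intercept, the given
#' nuisance design, optional white-matter/CSF series, and (optionally) the
#' global signal. Rank-deficient designs are reduced by dropping dependent
#' columns with a warning. Residuals are orthogonal to every retained
#' regressor.
#'
#' @param series volumes x k data matrix.
#' @param design volumes x q nuisance matrix (may have 0 columns or NULL).
#' @param wmCsf optional volumes x 2 matrix of white-matter and CSF series.
#' @param globalSignal optional numeric vector (e.g. mean in-brain series);
#'   included when \code{addGlobal} is TRUE.
#' @param addGlobal include global signal regression.
#' @return residual series, same dimensions as input.
#' @export
regressConfounds <- function(series, design = NULL, wmCsf = NULL,
                             globalSignal = NULL, addGlobal = FALSE) {
  series <- as.matrix(series)
  nT <- nrow(series)
  X <- cbind(intercept = rep(1, nT))
  if (!is.null(design) && NCOL(design) > 0) {
    if (NROW(design) != nT) stop("design rows must match series length")
    X <- cbind(X, as.matrix(design))
  }
  if (!is.null(wmCsf)) X <- cbind(X, as.matrix(wmCsf))
  if (addGlobal) {
    if (is.null(globalSignal)) globalSignal <- rowMeans(series)
    X <- cbind(X, global = globalSignal)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[seq.int(qrX$rank + 1, ncol(X))]
    warning("dropping ", length(drop), " rank-deficient confound column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  series - X %*% qr.coef(qrX, series)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-2 Butterworth bandpass applied forward and backward
#' (\code{signal::filtfilt}), giving a zero-phase order-4 response: the
#' pass band (default 0.01-0.1 Hz) is preserved and power one octave
#' outside the band is attenuated by more than 90 percent.
#'
#' @param series volumes x k matrix (or vector).
#' @param low,high band edges (Hz).
#' @param TR sampling interval (s).
#' @return filtered series.
#' @export
bandpassFilter <- function(series, low = 0.01, high = 0.1, TR = 2) {
  nyq <- 1 / (2 * TR)
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("infeasible band [%g, %g] Hz for TR = %g s (Nyquist %g Hz)",
                 low, high, TR, nyq))
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  vec <- is.null(dim(series))
  m <- if (vec) matrix(series, ncol = 1) else as.matrix(series)
  out <- apply(m, 2, function(col) {
    mu <- mean(col)
    signal::filtfilt(bf, col - mu)
  })
  if (vec) drop(out) else out
}

# Reflective-boundary 1D Gaussian smoothing matrix (mass conserving for
# symmetric kernels).
.gaussSmoothMat <- function(len, sigmaVox) {
  half <- max(1L, ceiling(4 * sigmaVox))
  k <- dnorm(seq(-half, half), sd = sigmaVox)
  k <- k / sum(k)
  S <- matrix(0, len, len)
  for (i in seq_len(len)) {
    idx <- i + seq(-half, half)
    # reflect about the edges (half-sample symmetric)
    idx <- ifelse(idx < 1, 1 - idx, idx)
    idx <- ifelse(idx > len, 2 * len + 1 - idx, idx)
    for (j in seq_along(idx)) S[i, idx[j]] <- S[i, idx[j]] + k[j]
  }
  S
}

#' Spatial Gaussian smoothing
#'
#' Separable 3D Gaussian smoothing of a volume (3D, or 4D frame by frame)
#' with sigma = FWHM / (2 sqrt(2 ln 2)) converted to voxels. Reflective
#' boundary handling conserves the image sum.
#'
#' @param vol 3D or 4D array; voxel size read from \code{voxelSize} or the
#'   attached affine.
#' @param fwhm full width at half maximum (mm).
#' @param voxelSize isotropic voxel size (mm); defaults to the affine
#'   attribute's scale.
#' @return smoothed array (affine attribute preserved).
#' @export
smoothGaussian <- function(vol, fwhm = 6, voxelSize = NULL) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  aff <- attr(vol, "affine")
  if (is.null(voxelSize)) {
    if (is.null(aff)) stop("voxel size unknown: supply voxelSize or an affine")
    voxelSize <- sqrt(sum(aff[1:3, 1]^2))
  }
  if (fwhm == 0) return(vol)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxelSize
  d <- dim(vol)
  is4d <- length(d) == 4
  dims3 <- d[1:3]
  S <- lapply(dims3, .gaussSmoothMat, sigmaVox = sigma)
  smooth3 <- function(a) {
    m <- S[[1]] %*% matrix(a, dims3[1])
    a <- aperm(array(m, dims3), c(2, 1, 3))
    m <- S[[2]] %*% matrix(a, dims3[2])
    a <- aperm(array(m, dims3[c(2, 1, 3)]), c(3, 2, 1))
    m <- S[[3]] %*% matrix(a, dims3[3])
    aperm(array(m, dims3[c(3, 1, 2)]), c(2, 3, 1))
  }
  out <- if (is4d) {
    res <- array(0, d)
    for (t in seq_len(d[4])) res[, , , t] <- smooth3(vol[, , , t])
    res
  } else smooth3(vol)
  attr(out, "affine") <- aff
  out
}

#' Full temporal preprocessing chain for one session
#'
#' Fixed stage order: discard initial volumes, (smooth when a 4D volume is
#' given), linear detrend, confound regression (Friston-24 motion expansion
#' plus optional WM/CSF and global signal), and bandpass filtering last.
#'
#' @param roi volumes x regions matrix of ROI series.
#' @param motion matching motion table.
#' @param nDiscard initial frames to drop.
#' @param TR sampling interval (s).
#' @param band band edges (Hz).
#' @param addGlobal include global signal regression.
#' @param wmCsf optional WM/CSF series (trimmed in lockstep).
#' @param bandpass apply the final bandpass stage (spectral data features
#'   for model inversion are taken before filtering).
#' @return list(roi, motion, log) where log records the stages applied.
#' @export
preprocessSession <- function(roi, motion, nDiscard = 10, TR = 2,
                              band = c(0.01, 0.1), addGlobal = TRUE,
                              wmCsf = NULL, bandpass = TRUE) {
  log <- character(0)
  if (nDiscard > 0) {
    tr <- discardInitial(roi, nDiscard, motion)
    roi <- tr$data; motion <- tr$motion
    if (!is.null(wmCsf)) wmCsf <- wmCsf[-seq_len(nDiscard), , drop = FALSE]
    log <- c(log, sprintf("discard:%d", nDiscard))
  }
  roi <- detrendSeries(roi)
  log <- c(log, "detrend:linear")
  roi <- regressConfounds(roi, friston24(motion), wmCsf = wmCsf,
                          addGlobal = addGlobal)
  log <- c(log, sprintf("confounds:friston24%s%s",
                        if (!is.null(wmCsf)) "+wmcsf" else "",
                        if (addGlobal) "+gsr" else ""))
  if (bandpass) {
    roi <- bandpassFilter(roi, band[1], band[2], TR)
    log <- c(log, sprintf("bandpass:%g-%g", band[1], band[2]))
  }
  list(roi = roi, motion = motion, log = log)
}
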