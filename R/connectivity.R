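#' Voxel-center coordinates of a grid
#'
#' @param dims integer triplet.
#' @param affine 4x4 voxel-to-mm affine (1-based voxel indices).
#' @return nVox x 3 matrix of mm coordinates, voxel linear order.
#' @export
voxelCoordinates <- function(dims, affine) {
  idx <- arrayInd(seq_len(prod(dims)), dims)
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

.volAffine <- function(vol, affine) {
  if (is.null(affine)) affine <- attr(vol, "affine")
  if (is.null(affine)) stop("volume has no affine")
  affine
}

.volMatrix <- function(vol) {
  d <- dim(vol)
  matrix(vol, prod(d[1:3]), d[4])   # voxels x time
}

#' Mean time course inside a spherical seed
#'
#' Averages the series of every voxel whose center lies within the given
#' radius (Euclidean distance in mm via the affine) of the seed center.
#'
#' @param vol 4D array (affine attached or supplied).
#' @param center MNI mm triplet.
#' @param radius sphere radius (mm).
#' @param affine optional 4x4 affine.
#' @return numeric time series.
#' @export
seedTimecourse <- function(vol, center, radius = 6, affine = NULL) {
  stopifnot(radius > 0)
  affine <- .volAffine(vol, affine)
  xyz <- voxelCoordinates(dim(vol)[1:3], affine)
  d2 <- colSums((t(xyz) - center)^2)
  sel <- d2 <= radius^2
  if (!any(sel)) stop("seed sphere does not intersect the grid")
  colMeans(.volMatrix(vol)[sel, , drop = FALSE])
}

#' Voxelwise Pearson correlation map against a seed series
#'
#' @param seed numeric series (length = number of frames).
#' @param vol 4D array.
#' @return list(r = 3D array of correlations, valid = 3D logical array;
#'   constant voxels get r = 0 and valid = FALSE).
#' @export
fcMap <- function(seed, vol) {
  d <- dim(vol)
  if (length(seed) != d[4]) stop("seed length must match volume frames")
  if (d[4] < 3) stop("need at least 3 frames")
  if (sd(seed) == 0) stop("seed series is constant")
  V <- .volMatrix(vol)
  Vc <- V - rowMeans(V)
  sc <- seed - mean(seed)
  denom <- sqrt(rowSums(Vc^2)) * sqrt(sum(sc^2))
  r <- as.vector(Vc %*% sc) / denom
  valid <- denom > 0 & is.finite(r)
  r[!valid] <- 0
  list(r = array(r, d[1:3]), valid = array(valid, d[1:3]))
}

#' Fisher z transform
#'
#' \code{z = atanh(r)}, variance-stabilizing for group tests on
#' correlations. Values with |r| >= 1 are clipped to 1 - 1e-7 with a
#' warning.
#'
#' @param r numeric array of correlations.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("clipping |r| >= 1 before Fisher z transform")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Group one-sample t maps split by sign
#'
#' Voxelwise one-sample t-test of subject z maps against zero; returns the
#' t map together with disjoint positive and negative masks thresholded at
#' a two-sided p < alpha. Voxels with zero between-subject variance are
#' excluded from both masks and flagged.
#'
#' @param zMaps list of 3D arrays (one per subject) on a common grid.
#' @param alpha two-sided significance level (default 0.05, uncorrected).
#' @return list(t, p, positive, negative, degenerate) of 3D arrays.
#' @export
groupSignedMaps <- function(zMaps, alpha = 0.05) {
  nSub <- length(zMaps)
  if (nSub < 3) stop("need at least 3 subjects")
  dims <- dim(zMaps[[1]])
  Z <- vapply(zMaps, as.vector, numeric(prod(dims)))
  mu <- rowMeans(Z)
  s <- sqrt(rowSums((Z - mu)^2) / (nSub - 1))
  degen <- s == 0
  tval <- mu / (s / sqrt(nSub))
  tval[degen] <- 0
  p <- 2 * pt(-abs(tval), df = nSub - 1)
  pos <- !degen & tval > 0 & p < alpha
  neg <- !degen & tval < 0 & p < alpha
  list(t = array(tval, dims), p = array(p, dims),
       positive = array(pos, dims), negative = array(neg, dims),
       degenerate = array(degen, dims))
}

#' Paired pre/post t map with FDR correction
#'
#' Voxelwise paired t-test between two sessions' z maps with
#' Benjamini-Hochberg control; used to ask whether target-based
#' connectivity changed after treatment.
#'
#' @param zPre,zPost lists of 3D arrays, subject-aligned.
#' @param q FDR level.
#' @return list(t, p, pAdj, significant).
#' @export
pairedFdrMap <- function(zPre, zPost, q = 0.05) {
  stopifnot(length(zPre) == length(zPost))
  dif <- mapply(function(a, b) as.vector(b) - as.vector(a), zPre, zPost)
  dims <- dim(zPre[[1]])
  n <- length(zPre)
  mu <- rowMeans(dif)
  s <- sqrt(rowSums((dif - mu)^2) / (n - 1))
  tval <- ifelse(s > 0, mu / (s / sqrt(n)), 0)
  p <- 2 * pt(-abs(tval), df = n - 1)
  pAdj <- p.adjust(p, method = "BH")
  list(t = array(tval, dims), p = array(p, dims),
       pAdj = array(pAdj, dims), significant = array(pAdj < q, dims))
}

#' Select the individualized stimulation target
#'
#' Finds the location inside the DLPFC mask whose time series is most
#' anticorrelated with the sgACC reference series (mean over the union of
#' the sgACC atlas labels). Voxel granularity by default; in subunit mode
#' the centroid of the most anticorrelated atlas subunit within the mask is
#' returned. Ties break on the smallest voxel index.
#'
#' @param vol 4D array.
#' @param dlpfcMask 3D logical array.
#' @param atlas 3D integer label array.
#' @param sgaccLabels atlas labels defining the sgACC (default 187, 188).
#' @param mode "voxel" or "subunit".
#' @param affine optional affine.
#' @return list(coordinate = MNI mm triplet, r, voxel = 1-based index
#'   triplet).
#' @export
selectTarget <- function(vol, dlpfcMask, atlas, sgaccLabels = c(187, 188),
                         mode = c("voxel", "subunit"), affine = NULL) {
  mode <- match.arg(mode)
  affine <- .volAffine(vol, affine)
  if (!any(dlpfcMask)) stop("empty DLPFC mask")
  ref <- atlas %in% sgaccLabels
  if (!any(ref)) stop("sgACC labels absent from atlas")
  V <- .volMatrix(vol)
  sgacc <- colMeans(V[as.vector(ref), , drop = FALSE])
  sel <- which(as.vector(dlpfcMask))
  if (mode == "voxel") {
    r <- suppressWarnings(cor(t(V[sel, , drop = FALSE]), sgacc))
    r[!is.finite(r)] <- 0
    best <- which.min(r)         # ties: smallest voxel index (which.min)
    if (r[best] >= 0)
      warning("no anticorrelated voxel in DLPFC mask; returning the minimum")
    vox <- arrayInd(sel[best], dim(vol)[1:3])
    mm <- (affine %*% c(vox, 1))[1:3]
    list(coordinate = as.numeric(mm), r = as.numeric(r[best]),
         voxel = as.integer(vox))
  } else {
    labs <- sort(setdiff(unique(atlas[dlpfcMask]), 0))
    if (!length(labs)) stop("DLPFC mask covers no atlas subunits")
    rs <- vapply(labs, function(L) {
      m <- colMeans(V[as.vector(atlas == L & dlpfcMask), , drop = FALSE])
      if (sd(m) == 0) 0 else cor(m, sgacc)
    }, numeric(1))
    best <- labs[which.min(rs)]
    vox <- arrayInd(which(atlas == best & dlpfcMask), dim(vol)[1:3])
    cen <- colMeans(vox)
    mm <- (affine %*% c(cen, 1))[1:3]
    list(coordinate = as.numeric(mm), r = min(rs), voxel = as.integer(round(cen)))
  }
}

#' Build ROI masks from signed maps and an atlas
#'
#' Each named ROI is the intersection of its atlas label set with the
#' signed group mask it originates from (negative map: PCUN, HIP, INS,
#' sgACC; positive map: CAU, mPFC). Lateral ROIs are restricted to the
#' left hemisphere (x < 0 mm via the affine); midline ROIs keep both
#' hemispheres.
#'
#' @param signedMasks list(positive, negative) of 3D logical arrays.
#' @param atlas 3D integer label array.
#' @param roiLabels named list: ROI name -> atlas label set.
#' @param polarity named character: ROI name -> "positive"/"negative".
#' @param leftOnly character vector of ROIs restricted to the left
#'   hemisphere.
#' @param affine optional affine (else from atlas attribute).
#' @return named list of 3D logical masks, with attributes "polarity" and
#'   "laterality".
#' @export
buildRoiMasks <- function(signedMasks, atlas, roiLabels,
                          polarity = c(CAU = "positive", mPFC = "positive",
                                       PCUN = "negative", HIP = "negative",
                                       INS = "negative", sgACC = "negative"),
                          leftOnly = c("CAU", "PCUN", "HIP", "INS"),
                          affine = NULL) {
  affine <- .volAffine(atlas, affine)
  dims <- dim(atlas)
  xmm <- array(voxelCoordinates(dims, affine)[, 1], dims)
  out <- list()
  for (nm in names(roiLabels)) {
    pol <- polarity[[nm]]
    if (is.null(pol)) stop("no polarity assigned for ROI ", nm)
    mask <- array(atlas %in% roiLabels[[nm]], dims) & signedMasks[[pol]]
    if (nm %in% leftOnly) mask <- mask & (xmm < 0)
    if (!any(mask))
      stop("empty mask for ROI ", nm,
           " (atlas/signed-map intersection is empty)")
    out[[nm]] <- mask
  }
  attr(out, "polarity") <- polarity[names(roiLabels)]
  attr(out, "laterality") <- ifelse(names(roiLabels) %in% leftOnly,
                                    "left", "bilateral")
  out
}

#' Mean time course of a mask
#'
#' @param vol 4D array.
#' @param mask 3D logical array.
#' @return numeric series (arithmetic mean over mask voxels per frame).
#' @export
extractRoiSeries <- function(vol, mask) {
  if (!any(mask)) stop("empty mask")
  colMeans(.volMatrix(vol)[as.vector(mask), , drop = FALSE])
}
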