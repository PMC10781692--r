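test_that("seed timecourse averages voxels inside the sphere", {
  set.seed(11)
  roi <- matrix(rnorm(80 * 3), 80, 3)
  emb <- quickVolume(roi, noiseSd = 0)
  vol <- emb$volume
  labels <- emb$labels
  aff <- emb$affine

  # homogeneous label block: mean equals the region series exactly
  vox <- arrayInd(which(labels == 2), dim(labels))
  cen <- (aff %*% c(colMeans(vox), 1))[1:3]
  expect_equal(seedTimecourse(vol, cen, radius = 7), roi[, 2])

  # sub-voxel radius at a voxel center: that voxel's series
  v1 <- arrayInd(which(labels == 1)[1], dim(labels))
  mm <- (aff %*% c(v1, 1))[1:3]
  expect_equal(seedTimecourse(vol, mm, radius = 1), roi[, 1])

  # sphere spanning two labels: weighted mean by voxel counts (brute force)
  xyz <- voxelCoordinates(dim(labels), aff)
  cen2 <- (mm + (aff %*% c(arrayInd(which(labels == 2)[1], dim(labels)), 1))[1:3]) / 2
  r <- 14
  sel <- which(colSums((t(xyz) - cen2)^2) <= r^2)
  brute <- colMeans(matrix(vol, prod(dim(labels)), 80)[sel, ])
  expect_equal(seedTimecourse(vol, cen2, radius = r), brute)

  expect_error(seedTimecourse(vol, c(500, 500, 500), radius = 2),
               "does not intersect")
})

test_that("correlation maps recover planted voxel correlations", {
  set.seed(12)
  nT <- 350
  seed <- rnorm(nT)
  vol <- array(rnorm(4 * 4 * 2 * nT), c(4, 4, 2, nT))
  vol[1, 1, 1, ] <- seed
  vol[2, 1, 1, ] <- -seed
  # planted r close to -0.9: -0.9*seed plus matched-variance noise
  vol[3, 1, 1, ] <- -0.9 * seed + sqrt(1 - 0.81) * rnorm(nT)
  vol[4, 1, 1, ] <- 5  # constant voxel
  fm <- fcMap(seed, vol)
  expect_equal(fm$r[1, 1, 1], 1)
  expect_equal(fm$r[2, 1, 1], -1)
  expect_lt(abs(fm$r[3, 1, 1] + 0.9), 0.05)
  expect_equal(fm$r[4, 1, 1], 0)
  expect_false(fm$valid[4, 1, 1])
  # invariance to affine rescaling of the seed
  fm2 <- fcMap(3 * seed + 10, vol)
  expect_equal(fm2$r, fm$r)
  expect_error(fcMap(rep(1, nT), vol), "constant")
})

test_that("Fisher z transform is exact and clips safely", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), atanh(0.5))
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_warning(z1 <- fisherZ(1), "clipping")
  expect_true(is.finite(z1))
})

test_that("signed group maps are calibrated and disjoint", {
  dims <- c(100, 100, 1)
  zeroMaps <- lapply(1:5, function(i) array(0, dims))
  gm0 <- groupSignedMaps(zeroMaps)
  expect_equal(sum(gm0$positive) + sum(gm0$negative), 0)
  expect_true(all(gm0$degenerate))

  set.seed(13)
  nullMaps <- lapply(1:26, function(i) array(rnorm(prod(dims)), dims))
  gm <- groupSignedMaps(nullMaps, alpha = 0.05)
  rate <- mean(gm$positive | gm$negative)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / prod(dims)) + 0.002)
  expect_false(any(gm$positive & gm$negative))

  # constant positive z across subjects with vanishing spread
  posMaps <- lapply(1:26, function(i)
    array(0.3 + rnorm(prod(dims), sd = 1e-6), dims))
  gmp <- groupSignedMaps(posMaps)
  expect_true(all(gmp$positive))
  expect_error(groupSignedMaps(nullMaps[1:2]), "at least 3")
})

test_that("paired pre/post maps with FDR control stay null under the null", {
  set.seed(14)
  dims <- c(40, 40, 1)
  pre <- lapply(1:12, function(i) array(rnorm(prod(dims)), dims))
  post <- lapply(1:12, function(i) array(rnorm(prod(dims)), dims))
  pm <- pairedFdrMap(pre, post, q = 0.05)
  expect_lt(mean(pm$significant), 0.01)
})

test_that("target selection finds the peak anticorrelated location", {
  set.seed(15)
  nT <- 200
  roi <- matrix(rnorm(nT * 4), nT, 4)
  emb <- quickVolume(roi, noiseSd = 0)
  vol <- emb$volume; labels <- emb$labels
  # plant a strongly anticorrelated voxel inside the "DLPFC" (label 1) mask
  sgaccSeries <- extractRoiSeries(vol, labels == 4)
  dlpfcMask <- labels == 1
  tgtVox <- arrayInd(which(dlpfcMask)[3], dim(labels))
  vol[tgtVox[1], tgtVox[2], tgtVox[3], ] <-
    -0.9 * sgaccSeries + sqrt(1 - 0.81) * sd(sgaccSeries) * rnorm(nT)
  tg <- selectTarget(vol, dlpfcMask, labels, sgaccLabels = 4)
  expect_equal(tg$voxel, as.integer(tgtVox))
  expect_lt(tg$r, -0.7)
  expect_equal(tg$coordinate, as.numeric((emb$affine %*% c(tgtVox, 1))[1:3]))
  # deterministic
  tg2 <- selectTarget(vol, dlpfcMask, labels, sgaccLabels = 4)
  expect_identical(tg, tg2)

  # single-voxel mask returns that voxel regardless of its correlation
  m1 <- array(FALSE, dim(labels))
  one <- arrayInd(which(labels == 2)[1], dim(labels))
  m1[one[1], one[2], one[3]] <- TRUE
  expect_warning(tg1 <- selectTarget(vol, m1, labels, sgaccLabels = 4),
                 "no anticorrelated")
  expect_equal(tg1$voxel, as.integer(one))
})

test_that("coordinates report as MNI mm triplets like the published table", {
  ref <- referenceTargets()
  expect_equal(nrow(ref), 26)
  expect_equal(as.numeric(ref[1, c("x", "y", "z")]), c(-26, 45, 28))
  expect_true(all(ref$x < 0))   # left-hemisphere targets
})

test_that("ROI masks follow polarity, atlas and laterality rules", {
  set.seed(16)
  roi <- matrix(rnorm(100 * 6), 100, 6)
  emb <- quickVolume(roi, gridShape = c(10, 10, 8), noiseSd = 0)
  labels <- emb$labels
  dims <- dim(labels)
  # labels 1, 2, 4, 5 sit in the left half of this grid; 3 and 6 on the right
  pos <- array(FALSE, dims); neg <- array(FALSE, dims)
  pos[labels %in% c(1, 3)] <- TRUE
  neg[labels %in% c(2, 4, 5, 6)] <- TRUE
  roiLabels <- list(CAU = 1, mPFC = 3, PCUN = 2, HIP = 4, INS = 5, sgACC = 6)
  masks <- buildRoiMasks(list(positive = pos, negative = neg), labels,
                         roiLabels)
  # negative-map ROIs and positive-map ROIs as assigned
  expect_equal(unname(attr(masks, "polarity")[c("PCUN", "HIP", "INS", "sgACC")]),
               rep("negative", 4))
  expect_equal(unname(attr(masks, "polarity")[c("CAU", "mPFC")]),
               rep("positive", 2))
  # left-lateral masks contain no right-hemisphere voxels
  xmm <- array(voxelCoordinates(dims, emb$affine)[, 1], dims)
  for (nm in c("CAU", "PCUN", "HIP", "INS"))
    expect_true(all(xmm[masks[[nm]]] < 0))
  # midline ROIs keep the whole label when the signed mask covers it
  expect_equal(sum(masks$sgACC), sum(labels == 6))
  # an empty intersection names the offending ROI
  emptyNeg <- array(FALSE, dims)
  expect_error(buildRoiMasks(list(positive = pos, negative = emptyNeg),
                             labels, roiLabels), "PCUN")
})

test_that("ROI series extraction is the arithmetic mask mean", {
  set.seed(17)
  vol <- array(rnorm(3 * 3 * 1 * 20), c(3, 3, 1, 20))
  m <- array(FALSE, c(3, 3, 1)); m[1, 1, 1] <- TRUE
  expect_equal(extractRoiSeries(vol, m), vol[1, 1, 1, ])
  # two voxels with series s and -s average to zero
  vol[2, 1, 1, ] <- -vol[1, 1, 1, ]
  m[2, 1, 1] <- TRUE
  expect_equal(extractRoiSeries(vol, m), rep(0, 20))
  expect_error(extractRoiSeries(vol, array(FALSE, c(3, 3, 1))), "empty")
})
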