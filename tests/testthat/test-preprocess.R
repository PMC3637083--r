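# Reference-region normalization and Gaussian smoothing.

constantVolume <- function(value, dims = c(20, 20, 20), voxelSize = 2) {
  VolumeImage(array(value, dim = dims), voxelSize = voxelSize)
}

test_that("reference mean of a constant volume is that constant", {
  expect_equal(sampleReferenceMean(constantVolume(7),
                                   referenceROI(c(-6, 6, -6, 6, -6, 6))), 7)
})

test_that("reference mean equals a brute-force voxel-center enumeration", {
  set.seed(4)
  vol <- VolumeImage(array(rnorm(20 * 22 * 18, 100, 10), dim = c(20, 22, 18)),
                     voxelSize = 2)
  roi <- referenceROI(c(-7, 5, -4, 8, -9, 1))
  # independent path: loop every voxel, test its center against the open box
  acc <- c()
  for (i in 1:20) for (j in 1:22) for (k in 1:18) {
    cx <- voxelCenters(vol, 1)[i]; cy <- voxelCenters(vol, 2)[j]
    cz <- voxelCenters(vol, 3)[k]
    if (cx > -7 && cx < 5 && cy > -4 && cy < 8 && cz > -9 && cz < 1)
      acc <- c(acc, volumeData(vol)[i, j, k])
  }
  expect_equal(sampleReferenceMean(vol, roi), mean(acc))
})

test_that("an ROI outside the grid is an explicit error", {
  expect_error(sampleReferenceMean(constantVolume(1),
                                   referenceROI(c(900, 950, 0, 5, 0, 5))),
               "no voxel centers")
})

test_that("normalization contract: unit reference mean, idempotence, scale invariance", {
  set.seed(5)
  vol <- VolumeImage(array(runif(16^3, 50, 150), dim = c(16, 16, 16)),
                     voxelSize = 2)
  roi <- referenceROI(c(-6, 6, -6, 6, -6, 6))
  nrm <- normalizeToReference(vol, roi)
  expect_equal(sampleReferenceMean(nrm, roi), 1, tolerance = 1e-9)
  # idempotent
  nrm2 <- normalizeToReference(nrm, roi)
  expect_equal(volumeData(nrm2), volumeData(nrm), tolerance = 1e-12)
  # voxel ratios unchanged
  d0 <- volumeData(vol); d1 <- volumeData(nrm)
  expect_equal(d1[1, 2, 3] / d1[4, 5, 6], d0[1, 2, 3] / d0[4, 5, 6])
  # invariant to global rescaling of the input
  scaled <- VolumeImage(volumeData(vol) * 37.5, voxelSize = 2)
  expect_equal(volumeData(normalizeToReference(scaled, roi)), d1,
               tolerance = 1e-12)
})

test_that("non-positive reference mean is rejected", {
  expect_error(normalizeToReference(constantVolume(0),
                                    referenceROI(c(-6, 6, -6, 6, -6, 6))),
               "must be > 0")
})

test_that("FWHM 12 mm converts to sigma ~5.0956 mm", {
  expect_equal(fwhmToSigma(12), 12 / 2.35482, tolerance = 1e-4)
  expect_equal(fwhmToSigma(12), 12 / (2 * sqrt(2 * log(2))))
})

test_that("smoothing a constant volume is the identity; FWHM 0 is the identity", {
  vol <- constantVolume(3.5, dims = c(12, 14, 10))
  expect_equal(volumeData(smoothGaussian(vol, 8)), volumeData(vol),
               tolerance = 1e-9)
  set.seed(6)
  vol2 <- VolumeImage(array(rnorm(12 * 14 * 10), dim = c(12, 14, 10)),
                      voxelSize = 2)
  expect_identical(volumeData(smoothGaussian(vol2, 0)), volumeData(vol2))
})

test_that("impulse response matches the separable Gaussian kernel", {
  dims <- c(21, 21, 21)
  arr <- array(0, dim = dims); arr[8, 11, 13] <- 1
  vol <- VolumeImage(arr, voxelSize = 2)
  sm <- volumeData(smoothGaussian(vol, 6))
  expect_equal(which(sm == max(sm)), which(arr == 1))
  # direct kernel evaluation at a handful of offsets (far from edges, so
  # reflection contributes nothing at 4 sigma truncation)
  sigma <- fwhmToSigma(6) / 2
  r <- ceiling(4 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  k0 <- which.max(k)
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 1, -2))) {
    expected <- k[k0 + off[1]] * k[k0 + off[2]] * k[k0 + off[3]]
    expect_equal(sm[8 + off[1], 11 + off[2], 13 + off[3]], expected,
                 tolerance = 1e-12)
  }
  # monotone decay along each axis within 3 sigma (in voxels)
  s3 <- floor(3 * sigma)
  expect_true(all(diff(sm[8:(8 + s3), 11, 13]) < 0))
  expect_true(all(diff(sm[8, 11:(11 + s3), 13]) < 0))
  expect_true(all(diff(sm[8, 11, 13:(13 + s3)]) < 0))
})

test_that("smoothing preserves total mass away from boundary effects", {
  set.seed(7)
  arr <- array(rnorm(18^3, 100, 5), dim = c(18, 18, 18))
  vol <- VolumeImage(arr, voxelSize = 2)
  expect_equal(sum(volumeData(smoothGaussian(vol, 6))), sum(arr),
               tolerance = 1e-9)
})

test_that("pipeline preprocessing applies smooth, then normalize, in that order", {
  sim <- simulateCohort(smallSpec(seed = 3L))
  roi <- referenceROI()
  pre <- preprocessCohort(sim$cohort, roi, fwhmMm = 9)
  v <- volumes(sim$cohort)[[1]]
  manual <- normalizeToReference(smoothGaussian(v, 9), roi)
  expect_equal(volumeData(volumes(pre)[[1]]), volumeData(manual))
  # the reverse order differs (normalizing constant is taken after blur)
  reversed <- smoothGaussian(normalizeToReference(v, roi), 9)
  expect_false(isTRUE(all.equal(volumeData(volumes(pre)[[1]]),
                                volumeData(reversed))))
})
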