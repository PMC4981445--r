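test_that("ground-truth phantoms hit the target volume fraction", {
  for (target in c(0.1, 0.3, 0.5)) {
    truth <- generateGroundTruth(PhantomSpec(sideMm = 1.6,
                                             targetBvtv = target,
                                             anisotropy = 1, seed = 11))
    expect_lt(abs(bvtv(truth) - target), 0.005)
  }
  expect_error(PhantomSpec(targetBvtv = 0.9), "targetBvtv")
  expect_error(PhantomSpec(sideMm = 1.0), "32")
})

test_that("identical spec and seed give voxel-identical phantoms", {
  s <- PhantomSpec(sideMm = 2.4, targetBvtv = 0.25, seed = 99)
  expect_identical(voxelData(generateGroundTruth(s)),
                   voxelData(generateGroundTruth(s)))
})

test_that("thickness scale maps to Tb.Th near twice its value", {
  # frozen calibration: at BV/TV 0.10 and thicknessScale 0.15 mm the
  # sphere-fitting Tb.Th of the excursion set measured 0.254 mm,
  # within the 30% band around 2 x 0.15 mm
  truth <- generateGroundTruth(PhantomSpec(targetBvtv = 0.10,
                                           thicknessScaleMm = 0.15,
                                           seed = 21))
  th <- localThickness(truth)
  tbTh <- mean(th[voxelData(truth)])
  expect_gt(tbTh, 0.7 * 2 * 0.15)
  expect_lt(tbTh, 1.3 * 2 * 0.15)
})

test_that("scan simulation reduces to exact intensities in the identity limit", {
  truth <- generateGroundTruth(PhantomSpec(sideMm = 1.6, seed = 2))
  scan <- simulateScan(truth, ImagingSpec(outVoxelMm = voxelSize(truth),
                                          psfFwhmMm = 0, noiseSd = 0,
                                          boneHeterogeneitySd = 0))
  expect_setequal(unique(as.vector(voxelData(scan))), c(0, 1000))
  expect_identical(voxelData(scan) == 1000, voxelData(truth))
  expect_equal(voxelSize(scan), voxelSize(truth))
})

test_that("scan simulation rejects invalid requests", {
  truth <- generateGroundTruth(PhantomSpec(sideMm = 1.6, seed = 2))
  expect_error(ImagingSpec(psfFwhmMm = -1), "psf")
  coarse <- simulateScan(truth, ImagingSpec(outVoxelMm = 0.15, noiseSd = 0,
                                            psfFwhmMm = 0,
                                            boneHeterogeneitySd = 0))
  expect_error(simulateScan(coarseToBinary <- BinaryVolume(
    voxelData(coarse) > 500, voxelSize(coarse)),
    ImagingSpec(outVoxelMm = 0.05)), "larger")
})

test_that("measured CNR tracks contrast over noise SD", {
  # half-bone/half-water phantom, negligible PSF
  a <- array(FALSE, c(40, 40, 40))
  a[, , 1:20] <- TRUE
  truth <- BinaryVolume(a, 0.05)
  sc <- simulateScan(truth, ImagingSpec(outVoxelMm = 0.05, psfFwhmMm = 0,
                                        noiseSd = 100,
                                        boneHeterogeneitySd = 0, seed = 5))
  # interior ROIs away from the interface
  roiBone <- array(FALSE, c(40, 40, 40)); roiBone[, , 1:15] <- TRUE
  roiBg <- array(FALSE, c(40, 40, 40)); roiBg[, , 26:40] <- TRUE
  measured <- cnr(sc, BinaryVolume(roiBone, 0.05), BinaryVolume(roiBg, 0.05))
  expect_lt(abs(measured - 10) / 10, 0.1)
})

test_that("stronger PSF shrinks the bimodal separation of the histogram", {
  truth <- generateGroundTruth(PhantomSpec(sideMm = 2.4, targetBvtv = 0.3,
                                           seed = 4))
  # valley depth oracle: histogram count at the midpoint between the two
  # class means, relative to the class peaks; deeper valley = more
  # separation. Track the between-class variance of the Otsu split as a
  # monotone separation summary.
  sep <- vapply(c(0, 0.1, 0.2, 0.3), function(psf) {
    sc <- simulateScan(truth, ImagingSpec(outVoxelMm = 0.05,
                                          psfFwhmMm = psf, noiseSd = 0,
                                          boneHeterogeneitySd = 0))
    v <- as.vector(voxelData(sc))
    m <- otsuSegment(sc)
    mean(v[voxelData(m)]) - mean(v[!voxelData(m)])
  }, numeric(1))
  expect_true(all(diff(sep) < 0))
})

test_that("specimen sets span the trabecular BV/TV range reproducibly", {
  specs <- makeSpecimenSet(5, baseSeed = 13,
                           phantom = PhantomSpec(sideMm = 1.6))
  expect_length(specs, 5L)
  targets <- vapply(specs, function(s) s$spec@targetBvtv, numeric(1))
  expect_true(all(diff(targets) > 0))
  expect_equal(range(targets), c(0.05, 0.45))
  seeds <- vapply(specs, function(s) s$spec@seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  # one fine scan plus at least two degraded scans each
  for (s in specs) {
    expect_true("fine" %in% names(s$scans))
    expect_gte(length(s$scans), 3L)
    expect_equal(voxelSize(s$scans$fine), voxelSize(s$truth))
  }
  expect_error(makeSpecimenSet(2), "n >= 3")
})

test_that("block averaging preserves the mean and the grid factor", {
  a <- array(rnorm(24^3), c(24, 24, 24))
  b <- trabecula:::blockAverage(a, 3L)
  expect_equal(dim(b), c(8L, 8L, 8L))
  expect_equal(mean(b), mean(a), tolerance = 1e-12)
  expect_equal(b[1, 1, 1], mean(a[1:3, 1:3, 1:3]))
})
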