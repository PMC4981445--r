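test_that("skeletonization leaves thin structures untouched", {
  rod <- rodPhantom()
  sk <- skeletonize(rod)
  expect_identical(voxelData(sk@skeletonMask), voxelData(rod))
  expect_equal(sk@nNodes, 0L)
  expect_equal(sk@nTermini, 2L)
  expect_error(skeletonize(BinaryVolume(array(FALSE, c(4, 4, 4)), 0.1)),
               "empty")
})

test_that("a solid cube thins to a unit-width connected subset", {
  a <- array(FALSE, c(26, 26, 26))
  a[4:23, 4:23, 4:23] <- TRUE
  cube <- BinaryVolume(a, 0.1)
  sk <- skeletonize(cube)
  skm <- voxelData(sk@skeletonMask)
  expect_true(all(a[skm]))              # containment
  expect_lt(sum(skm), sum(a))          # strictly thinner
  # connectivity preserved: one component in, one out
  lab <- trabecula:::labelComponentsCpp(as.vector(skm),
                                        as.integer(dim(skm)), 26L)
  expect_equal(max(lab), 1L)
  # unit width: no voxel retains all six face neighbours
  cnt6 <- array(0L, dim(skm))
  for (ax in 1:3) for (by in c(1L, -1L))
    cnt6 <- cnt6 + trabecula:::shiftArray(skm, ax, by, FALSE)
  expect_true(all(cnt6[skm] < 6L))
})

test_that("junctions and free ends are counted per constructed phantom", {
  cross <- crossPhantom()
  sk <- skeletonize(cross)
  expect_equal(sk@nNodes, 1L)
  expect_equal(sk@nTermini, 6L)
  census <- countNodesTermini(sk, volumeMm3 = 1)
  expect_equal(unname(census["tbNd"]), 1)
  expect_equal(unname(census["tbTm"]), 6)

  h <- hPhantom()
  skh <- skeletonize(h)
  expect_equal(skh@nNodes, 2L)
  expect_equal(skh@nTermini, 4L)

  # a rod spanning face to face has no interior free ends
  a <- array(FALSE, c(9, 9, 9)); a[5, 5, ] <- TRUE
  sk2 <- skeletonize(BinaryVolume(a, 0.1))
  expect_equal(sk2@nTermini, 0L)
})

test_that("local thickness matches analytic slab and point values", {
  # interior slab, 0.40 mm thick at 0.02 mm voxels
  a <- array(FALSE, c(40, 40, 40)); a[, , 11:30] <- TRUE
  th <- localThickness(BinaryVolume(a, 0.02))
  expect_lt(abs(mean(th[a]) - 0.40), 0.04 + 1e-12)

  # a single isolated voxel is one voxel thick
  b <- array(FALSE, c(9, 9, 9)); b[5, 5, 5] <- TRUE
  thb <- localThickness(BinaryVolume(b, 0.1))
  expect_equal(thb[5, 5, 5], 0.1)

  # dilation increases the mean thickness
  grow1 <- function(m) {
    out <- m
    for (ax in 1:3) for (by in c(1L, -1L))
      out <- out | trabecula:::shiftArray(m, ax, by, FALSE)
    out
  }
  rod <- voxelData(rodPhantom(11))
  thin <- localThickness(BinaryVolume(rod, 0.1))
  fat <- localThickness(BinaryVolume(grow1(rod), 0.1))
  expect_gt(mean(fat[grow1(rod)]), mean(thin[rod]))
})

test_that("structure metrics reproduce analytic periodic geometry", {
  slab <- slabPhantom()        # period 1.0 mm, thickness 0.2 mm
  m <- computeMetrics(slab)
  df <- as.data.frame(m)
  expect_identical(df$BVTV, 0.2)
  expect_lt(abs(df$Tb.Th - 0.20), 0.02 + 1e-12)   # within one voxel
  expect_lt(abs(df$Tb.Sc - 1.0), 0.10)
  expect_lt(abs(df$Tb.N - 1.0), 0.10)
  expect_lt(abs(df$Tb.Sp - 0.80), 0.04)
  expect_identical(df$Tb.N, 1 / df$Tb.Sc)
})

test_that("degenerate masks fail with BV/TV-style diagnostics", {
  expect_error(computeMetrics(BinaryVolume(array(TRUE, c(8, 8, 8)), 0.1)),
               "full")
  expect_error(computeMetrics(BinaryVolume(array(FALSE, c(8, 8, 8)), 0.1)),
               "empty")
  # counting is exact
  a <- array(FALSE, c(10, 10, 10)); a[seq_len(100)] <- TRUE
  expect_identical(bvtv(BinaryVolume(a, 0.1)), 0.1)
})

test_that("metrics are axis-permutation invariant on isotropic phantoms", {
  truth <- generateGroundTruth(PhantomSpec(sideMm = 2.4, targetBvtv = 0.25,
                                           anisotropy = 1, seed = 6))
  m1 <- as.data.frame(computeMetrics(truth))
  rotated <- BinaryVolume(aperm(voxelData(truth), c(3, 1, 2)),
                          voxelSize(truth))
  m2 <- as.data.frame(computeMetrics(rotated))
  for (col in c("Tb.Sp", "Tb.Sc", "Tb.N", "Tb.Th", "BVTV")) {
    expect_lt(abs(m1[[col]] - m2[[col]]) / m1[[col]], 0.05)
  }
  # skeleton census is more discretization-sensitive; allow 15%
  for (col in c("Tb.Nd", "Tb.Tm")) {
    expect_lt(abs(m1[[col]] - m2[[col]]) / m1[[col]], 0.15)
  }
})

test_that("trabecular number is the reciprocal of spacing", {
  truth <- generateGroundTruth(PhantomSpec(sideMm = 2.4, seed = 3))
  m <- computeMetrics(truth)
  expect_identical(m@tbN, 1 / m@tbSc)
  # printed mean pairs of the emulated study are mutually consistent
  # within two-decimal rounding: 1/0.85 vs 1.20 and 1/1.07 vs 0.94
  expect_lt(abs(1 / 0.85 - 1.20), 0.03)
  expect_lt(abs(1 / 1.07 - 0.94), 0.01)
})

test_that("coarser rescans inflate apparent BV/TV and thickness", {
  truth <- generateGroundTruth(PhantomSpec(targetBvtv = 0.10, seed = 31))
  res <- lapply(c(0.10, 0.15, 0.20), function(vs) {
    sc <- simulateScan(truth, ImagingSpec(outVoxelMm = vs,
                                          psfFwhmMm = 1.3 * vs,
                                          noiseSd = 80, seed = 2))
    mask <- argSegment(sc)@selectedMask
    th <- localThickness(mask)
    c(bv = bvtv(mask), th = mean(th[voxelData(mask)]))
  })
  bv <- vapply(res, `[[`, 0, "bv")
  th <- vapply(res, `[[`, 0, "th")
  expect_true(all(diff(bv) > 0))
  expect_true(all(diff(th) > 0))
})
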