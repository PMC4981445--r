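test_that("the hexahedral element matrix satisfies its algebraic contracts", {
  K <- elementStiffness(0.05, 12, 0.3)
  expect_identical(K, t(K))
  # six rigid-body modes: translations and infinitesimal rotations
  coords <- trabecula:::hexOffsets * 0.05
  modes <- cbind(
    as.vector(t(cbind(rep(1, 8), 0, 0))),
    as.vector(t(cbind(0, rep(1, 8), 0))),
    as.vector(t(cbind(0, 0, rep(1, 8)))),
    as.vector(t(cbind(-coords[, 2], coords[, 1], 0))),
    as.vector(t(cbind(-coords[, 3], 0, coords[, 1]))),
    as.vector(t(cbind(0, -coords[, 3], coords[, 2]))))
  expect_lt(max(abs(K %*% modes)), 1e-12)
  expect_equal(qr(K)$rank, 18L)
  expect_error(elementStiffness(0.05, 12, 0.5), "nu")
})

test_that("the element matrix matches a higher-order quadrature oracle", {
  K <- elementStiffness(0.02, 12, 0.3)
  Ko <- oracleElementK(0.02, 12, 0.3)
  expect_lt(max(abs(K - Ko)) / max(abs(Ko)), 1e-10)
})

test_that("model building keeps the largest face-connected component", {
  a <- array(FALSE, c(6, 6, 6))
  a[1:4, 1:4, 1:4] <- TRUE
  a[6, 6, 6] <- TRUE  # detached corner voxel
  expect_message(model <- buildModel(BinaryVolume(a, 0.05)), "removed")
  expect_false(voxelData(model@occupancy)[6, 6, 6])
  expect_equal(model@removedFraction, 1 / sum(a))

  # fully connected masks pass through unchanged
  b <- array(TRUE, c(4, 4, 4))
  m2 <- buildModel(BinaryVolume(b, 0.05))
  expect_identical(voxelData(m2@occupancy), b)
  expect_equal(m2@removedFraction, 0)

  # equal components: deterministic choice with a warning
  c2 <- array(FALSE, c(7, 3, 3))
  c2[1:2, 1:2, 1:2] <- TRUE
  c2[5:6, 1:2, 1:2] <- TRUE
  expect_warning(m3 <- suppressMessages(buildModel(BinaryVolume(c2, 0.05))),
                 "equally large")
  expect_true(voxelData(m3@occupancy)[1, 1, 1])
  expect_false(voxelData(m3@occupancy)[5, 1, 1])
})

test_that("KUBC solutions satisfy exact special cases", {
  solid <- buildModel(BinaryVolume(array(TRUE, c(6, 6, 6)), 0.05))
  zero <- solveCase(solid, matrix(0, 3, 3))
  expect_lt(max(abs(zero$displacements)), 1e-14)

  # homogeneous cube under uniaxial strain: exact affine field
  eps <- trabecula:::voigtStrainTensor(3L)
  sol <- solveCase(solid, eps)
  expect_lt(max(abs(sol$displacements - sol$coords %*% t(eps))), 1e-9)
  expect_lt(sol$residual, 1e-8)
})

test_that("a solid cube returns the tissue constants", {
  st <- homogenize(buildModel(BinaryVolume(array(TRUE, c(8, 8, 8)), 0.05)))
  E <- youngsModuli(st)
  expect_lt(max(abs(E - 12)) / 12, 1e-9)
  expect_lt(abs(shearMin(st) - 12 / 2.6) / (12 / 2.6), 1e-9)
  # C equals the isotropic elasticity matrix
  expect_lt(max(abs(stiffnessMatrix(st) -
                      trabecula:::isotropicD(12, 0.3))), 1e-6)
})

test_that("a slender strut recovers the closed-form axial modulus", {
  d <- c(10, 10, 10)
  a <- array(FALSE, d); a[5, 5, ] <- TRUE
  st <- homogenize(buildModel(BinaryVolume(a, 0.05)))
  C <- stiffnessMatrix(st)
  S <- solve(C)
  Eax <- 1 / diag(S)[1:3]
  expect_lt(abs(Eax[3] - 12 * 0.01) / (12 * 0.01), 0.05)
  expect_lt(Eax[1] / Eax[3], 0.2)
  expect_lt(Eax[2] / Eax[3], 0.2)
  expect_equal(youngsModuli(st)[["E3"]], max(Eax))
})

test_that("apparent stiffness is linear in tissue modulus and size-invariant", {
  m <- randomMask(8, 0.4, seed = 5)
  mod1 <- suppressMessages(buildModel(m, tissueE = 12))
  mod2 <- suppressMessages(buildModel(m, tissueE = 24))
  C1 <- stiffnessMatrix(homogenize(mod1))
  C2 <- stiffnessMatrix(homogenize(mod2))
  expect_lt(max(abs(C2 - 2 * C1)) / max(abs(C1)), 1e-9)

  big <- BinaryVolume(voxelData(m), 0.30)
  modBig <- suppressMessages(buildModel(big))
  expect_lt(max(abs(stiffnessMatrix(homogenize(modBig)) - C1)) /
              max(abs(C1)), 1e-9)
})

test_that("porous masks match the dense mutual-energy oracle", {
  for (s in 1:2) {
    m <- randomMask(8, 0.5, seed = s)
    model <- suppressMessages(buildModel(m))
    Cp <- stiffnessMatrix(homogenize(model))
    Co <- oracleHomogenize(voxelData(model@occupancy), voxelSize(m))
    expect_lt(max(abs(Cp - Co)) / max(abs(Co)), 1e-6)
    # C symmetric positive definite
    expect_lt(max(abs(Cp - t(Cp))) / max(abs(Cp)), 1e-6)
    expect_gt(min(eigen(Cp, symmetric = TRUE, only.values = TRUE)$values),
              0)
  }
})

test_that("anisotropic phantoms are stiffest along the elongation axis", {
  for (s in 1:5) {
    truth <- generateGroundTruth(PhantomSpec(sideMm = 1.6,
                                             targetBvtv = 0.3,
                                             anisotropy = 1.6, seed = s))
    st <- homogenize(suppressMessages(buildModel(truth)))
    S <- solve(stiffnessMatrix(st))
    Eax <- 1 / diag(S)[1:3]
    expect_gte(Eax[3], max(Eax[1], Eax[2]))
  }
})
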