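## Voxel micro-FE homogenization. Every bone voxel becomes one linear
## isotropic eight-node hexahedral element (edge = voxel size). Apparent
## stiffness is obtained from six unit macroscopic strain cases under
## kinematic uniform boundary conditions (all surface nodes displaced by
## u = eps.x), averaging element stress over the total cube volume.

# hex node order: (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)
hexOffsets <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0,
                       0,0,1, 1,0,1, 1,1,1, 0,1,1),
                     ncol = 3, byrow = TRUE)

gaussRule <- function(n) {
  switch(as.character(n),
    "1" = list(x = 0, w = 2),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9),
    "4" = list(x = c(-0.8611363115940526, -0.3399810435848563,
                     0.3399810435848563, 0.8611363115940526),
               w = c(0.3478548451374538, 0.6521451548625461,
                     0.6521451548625461, 0.3478548451374538)),
    stop("unsupported quadrature order"))
}

# dN/d(xi,eta,zeta) for the trilinear hex, 3 x 8
hexShapeDeriv <- function(xi, eta, zeta) {
  s <- 2 * hexOffsets - 1  # natural coordinates of the nodes, +-1
  dN <- matrix(0, 3, 8)
  for (i in 1:8) {
    dN[1, i] <- s[i, 1] * (1 + eta * s[i, 2]) * (1 + zeta * s[i, 3]) / 8
    dN[2, i] <- (1 + xi * s[i, 1]) * s[i, 2] * (1 + zeta * s[i, 3]) / 8
    dN[3, i] <- (1 + xi * s[i, 1]) * (1 + eta * s[i, 2]) * s[i, 3] / 8
  }
  dN
}

# 6x24 strain-displacement matrix from physical shape gradients (3x8).
# Voigt order (11, 22, 33, 12, 13, 23), engineering shear strains.
hexBMatrix <- function(dNdx) {
  B <- matrix(0, 6, 24)
  for (i in 1:8) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dNdx[1, i]
    B[2, c0 + 2] <- dNdx[2, i]
    B[3, c0 + 3] <- dNdx[3, i]
    B[4, c0 + 1] <- dNdx[2, i]; B[4, c0 + 2] <- dNdx[1, i]
    B[5, c0 + 1] <- dNdx[3, i]; B[5, c0 + 3] <- dNdx[1, i]
    B[6, c0 + 2] <- dNdx[3, i]; B[6, c0 + 3] <- dNdx[2, i]
  }
  B
}

# isotropic elasticity matrix, engineering-shear Voigt convention
isotropicD <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Element stiffness matrix of a cube-shaped trilinear hexahedron
#'
#' 24x24 stiffness by Gauss quadrature (2x2x2 by default, which is exact
#' for the trilinear element with affine geometry). Symmetric with the
#' six rigid-body modes in its nullspace.
#'
#' @param voxelMm element edge length (mm).
#' @param E tissue Young's modulus (any unit; the result carries it).
#' @param nu Poisson ratio in [0, 0.5).
#' @param nGauss quadrature points per axis (1-4).
#' @return 24x24 numeric matrix; dof order is node-major (u1x, u1y, u1z,
#'   u2x, ...), node order (0,0,0),(1,0,0),(1,1,0),(0,1,0) then the upper
#'   face in the same sweep.
#' @export
elementStiffness <- function(voxelMm, E, nu, nGauss = 2L) {
  stopifnot(E > 0)
  if (nu < 0 || nu >= 0.5) stop("nu must be in [0, 0.5)")
  D <- isotropicD(E, nu)
  g <- gaussRule(nGauss)
  detJ <- (voxelMm / 2)^3
  K <- matrix(0, 24, 24)
  for (a in seq_along(g$x)) for (b in seq_along(g$x)) for (c in seq_along(g$x)) {
    dNdx <- hexShapeDeriv(g$x[a], g$x[b], g$x[c]) * (2 / voxelMm)
    B <- hexBMatrix(dNdx)
    K <- K + t(B) %*% D %*% B * detJ * g$w[a] * g$w[b] * g$w[c]
  }
  (K + t(K)) / 2
}

#' Build a micro-FE model from a bone mask
#'
#' Retains only the largest face-connected (6-neighbour) component:
#' floating or edge-only-connected fragments carry no well-posed
#' hexahedral stiffness and would make the system singular. Components
#' that do not reach the volume boundary cannot be loaded by the
#' boundary displacements, so the largest boundary-touching component is
#' preferred when one exists. The removed fraction is reported.
#'
#' @param mask a non-empty [BinaryVolume-class].
#' @param tissueE tissue Young's modulus in GPa (default 12).
#' @param tissueNu tissue Poisson ratio (default 0.3).
#' @return an [FEModel-class].
#' @export
buildModel <- function(mask, tissueE = 12, tissueNu = 0.3) {
  stopifnot(is(mask, "BinaryVolume"))
  if (!any(mask@voxels)) stop("empty mask")
  d <- dim(mask)
  lab <- labelComponentsCpp(as.vector(mask@voxels), as.integer(d), 6L)
  labA <- array(lab, d)
  sizes <- tabulate(lab)
  touching <- unique(c(labA[c(1L, d[1]), , ], labA[, c(1L, d[2]), ],
                       labA[, , c(1L, d[3])]))
  touching <- touching[touching > 0L]
  candSizes <- sizes
  if (length(touching) > 0) {
    candSizes[] <- 0L
    candSizes[touching] <- sizes[touching]
  }
  keepLab <- which.max(candSizes)  # ties: lowest label = lowest index
  if (keepLab != which.max(sizes))
    message("largest component does not reach the volume boundary; ",
            "using the largest boundary-touching component")
  if (sum(candSizes == max(candSizes)) > 1L)
    warning("multiple equally large components; keeping the one containing ",
            "the lowest voxel index")
  occ <- BinaryVolume(array(lab == keepLab, d), voxelSize(mask))
  removed <- 1 - sizes[keepLab] / sum(sizes)
  if (removed > 0)
    message(sprintf("removed %.3f%% of bone voxels in %d minor component(s)",
                    100 * removed, length(sizes) - 1L))
  new("FEModel", occupancy = occ, tissueE = tissueE, tissueNu = tissueNu,
      removedFraction = removed)
}

# node lattice, element connectivity and KUBC partition for an occupancy
feMesh <- function(model) {
  occ <- model@occupancy@voxels
  d <- dim(occ)
  h <- voxelSize(model@occupancy)
  vox <- which(occ, arr.ind = TRUE)  # 1-based voxel indices
  nxp <- d[1] + 1L; nyp <- d[2] + 1L
  keys <- matrix(0L, nrow(vox), 8)
  for (k in 1:8) {
    i <- vox[, 1] - 1L + hexOffsets[k, 1]
    j <- vox[, 2] - 1L + hexOffsets[k, 2]
    l <- vox[, 3] - 1L + hexOffsets[k, 3]
    keys[, k] <- i + nxp * (j + nyp * l)
  }
  ukeys <- sort(unique(as.vector(keys)))
  elemNodes <- matrix(match(keys, ukeys), nrow(vox), 8) - 1L  # 0-based
  i <- ukeys %% nxp
  j <- (ukeys %/% nxp) %% nyp
  l <- ukeys %/% (nxp * nyp)
  coords <- cbind(i, j, l) * h
  boundary <- i == 0L | i == d[1] | j == 0L | j == d[2] | l == 0L | l == d[3]
  list(elemNodes = elemNodes, coords = coords, boundary = boundary,
       dims = d, h = h)
}

# the six canonical unit macroscopic strains as 3x3 tensors
voigtStrainTensor <- function(case) {
  e <- matrix(0, 3, 3)
  if (case <= 3) e[case, case] <- 1
  else {
    ij <- list(c(1, 2), c(1, 3), c(2, 3))[[case - 3]]
    e[ij[1], ij[2]] <- e[ij[2], ij[1]] <- 0.5  # engineering gamma = 1
  }
  e
}

# displacement dof vector (3*nnodes) for u = eps . x
kubcDisplacement <- function(coords, eps) {
  as.vector(t(coords %*% t(eps)))
}

# assemble K_ff (sparse, symmetric) and the KUBC load vectors for a set
# of macroscopic strain tensors
feSystem <- function(model, strains) {
  mesh <- feMesh(model)
  Ke <- elementStiffness(mesh$h, model@tissueE, model@tissueNu)
  nnodes <- nrow(mesh$coords)
  freeIndex <- rep(-1L, 3L * nnodes)
  freeNodes <- which(!mesh$boundary)
  if (length(freeNodes) > 0) {
    dofs <- as.vector(t(cbind(3L * (freeNodes - 1L), 3L * (freeNodes - 1L) + 1L,
                              3L * (freeNodes - 1L) + 2L)))
    freeIndex[dofs + 1L] <- seq_along(dofs) - 1L
  }
  ub <- vapply(strains, function(e) kubcDisplacement(mesh$coords, e),
               numeric(3L * nnodes))
  asm <- feAssembleCpp(mesh$elemNodes, Ke, freeIndex, ub)
  Kff <- NULL
  if (asm$nfree > 0)
    Kff <- Matrix::sparseMatrix(i = asm$i + 1L, j = asm$j + 1L, x = asm$x,
                                dims = c(asm$nfree, asm$nfree),
                                symmetric = TRUE)
  list(mesh = mesh, Ke = Ke, freeIndex = freeIndex, ub = ub,
       Kff = Kff, rhs = asm$rhs, nfree = asm$nfree)
}

# full displacement matrix (3*nnodes x ncase) given free solutions
feFullDisplacement <- function(sys, uf) {
  U <- sys$ub
  if (sys$nfree > 0) {
    freeMask <- sys$freeIndex >= 0
    U[freeMask, ] <- as.matrix(uf)[sys$freeIndex[freeMask] + 1L, , drop = FALSE]
  }
  U
}

#' Solve one KUBC load case
#'
#' Prescribes u = eps.x on all surface nodes of the cube and solves the
#' interior by sparse Cholesky factorization (relative residual far below
#' the 1e-8 contract; the achieved residual is reported).
#'
#' @param model an [FEModel-class].
#' @param strain a 3x3 symmetric macroscopic strain tensor, or an integer
#'   1-6 selecting a canonical unit case in Voigt order (11, 22, 33, 12,
#'   13, 23; shear cases are unit engineering strain).
#' @return list with `displacements` (nnodes x 3, mm), `coords`
#'   (nnodes x 3, mm), `residual` (relative), and `strain`.
#' @export
solveCase <- function(model, strain) {
  stopifnot(is(model, "FEModel"))
  validObject(model)
  if (length(strain) == 1 && strain %in% 1:6)
    strain <- voigtStrainTensor(as.integer(strain))
  stopifnot(is.matrix(strain), all(dim(strain) == c(3, 3)))
  if (max(abs(strain - t(strain))) > 1e-12) stop("strain must be symmetric")
  sys <- feSystem(model, list(strain))
  if (sys$nfree > 0) {
    ch <- Matrix::Cholesky(sys$Kff, LDL = FALSE, super = TRUE)
    uf <- Matrix::solve(ch, sys$rhs)
    num <- sqrt(sum((sys$Kff %*% uf - sys$rhs)^2))
    den <- sqrt(sum(sys$rhs^2))
    residual <- if (den > 0) num / den else 0
    if (residual > 1e-8)
      stop(sprintf("solver residual %.3g exceeds tolerance 1e-8", residual))
  } else {
    uf <- matrix(0, 0, 1)
    residual <- 0
  }
  U <- feFullDisplacement(sys, uf)
  list(displacements = matrix(U, ncol = 3, byrow = TRUE),
       coords = sys$mesh$coords, residual = residual, strain = strain)
}

#' Homogenize: apparent stiffness tensor and engineering constants
#'
#' Runs the six canonical KUBC load cases, assembles the apparent
#' stiffness from volume-averaged element stresses (pores contribute
#' zero; the average is over the total cube volume), symmetrizes C, and
#' extracts E1-E3 and the shear moduli from the compliance S = C^-1
#' (E_i = 1/S_ii, G_ij from the shear diagonal). Young's moduli are
#' relabeled so E3 is the maximum; Gmin is the smallest shear modulus.
#'
#' @param model an [FEModel-class].
#' @return a [StiffnessResult-class] (units of `tissueE`, GPa by default).
#' @examples
#' solid <- BinaryVolume(array(TRUE, c(8, 8, 8)), 0.05)
#' homogenize(buildModel(solid))  # returns the tissue constants
#' @export
homogenize <- function(model) {
  stopifnot(is(model, "FEModel"))
  validObject(model)
  strains <- lapply(1:6, voigtStrainTensor)
  sys <- feSystem(model, strains)
  if (sys$nfree > 0) {
    ch <- Matrix::Cholesky(sys$Kff, LDL = FALSE, super = TRUE)
    uf <- Matrix::solve(ch, sys$rhs)
  } else {
    uf <- matrix(0, 0, 6)
  }
  U <- feFullDisplacement(sys, uf)

  # volume-averaged stress per case; centroid stress is the exact element
  # mean for the trilinear element
  mesh <- sys$mesh
  D <- isotropicD(model@tissueE, model@tissueNu)
  B0 <- hexBMatrix(hexShapeDeriv(0, 0, 0) * (2 / mesh$h))
  dofIdx <- matrix(0L, nrow(mesh$elemNodes), 24)
  for (k in 1:8) {
    base <- 3L * mesh$elemNodes[, k]
    dofIdx[, 3 * k - 2] <- base + 1L
    dofIdx[, 3 * k - 1] <- base + 2L
    dofIdx[, 3 * k] <- base + 3L
  }
  Vtot <- prod(mesh$dims) * mesh$h^3
  Ve <- mesh$h^3
  C <- matrix(0, 6, 6)
  DB0 <- D %*% B0
  for (case in 1:6) {
    u <- U[, case]
    Ue <- matrix(u[dofIdx], ncol = 24)
    sig <- Ue %*% t(DB0)          # ne x 6 element-mean stresses
    C[, case] <- colSums(sig) * Ve / Vtot
  }

  asym <- max(abs(C - t(C))) / max(abs(C))
  if (asym > 1e-6)
    message(sprintf("stiffness asymmetry %.3g before symmetrization", asym))
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("apparent stiffness is singular or indefinite; model may be ",
         "insufficiently connected to the boundary")
  S <- solve(C)
  E <- sort(1 / diag(S)[1:3])
  G <- setNames(1 / diag(S)[4:6], c("G12", "G13", "G23"))
  # slot named "C" would partially match new()'s Class argument
  res <- new("StiffnessResult")
  res@C <- C
  res@E <- unname(E)
  res@G <- G
  res@Gmin <- min(G)
  res@asymmetry <- asym
  res
}

#' Centered physical crop of a volume
#'
#' Extracts a centered sub-cube with the requested physical side, rounded
#' to whole voxels. When the margin is odd the extra voxel goes to the
#' high-index side (the center is rounded half-down).
#'
#' @param vol a [GrayVolume-class] or [BinaryVolume-class].
#' @param sideMm requested physical side (mm); must not exceed the volume.
#' @return the cropped volume, same class as the input.
#' @export
extractCube <- function(vol, sideMm) {
  stopifnot(is(vol, "VoxelVolume"))
  h <- voxelSize(vol)
  n <- as.integer(round(sideMm / h))
  d <- dim(vol)
  if (n > min(d)) stop(sprintf(
    "requested %.3g mm (%d voxels) exceeds the volume extent (%d voxels)",
    sideMm, n, min(d)))
  if (n < 1L) stop("requested side is below one voxel")
  start <- (d - n) %/% 2L + 1L
  v <- vol@voxels[start[1]:(start[1] + n - 1L),
                  start[2]:(start[2] + n - 1L),
                  start[3]:(start[3] + n - 1L), drop = FALSE]
  if (is(vol, "BinaryVolume")) BinaryVolume(v, h) else GrayVolume(v, h)
}

#' @rdname extractCube
#' @details `extractFeCube` and `extractAnalysisCube` are the same
#'   centered crop with the study's default sides: 5.3 mm for the FE
#'   cube, 8 mm for the trabecular analysis cube.
#' @export
extractFeCube <- function(vol, sideMm = 5.3) extractCube(vol, sideMm)

#' @rdname extractCube
#' @export
extractAnalysisCube <- function(vol, sideMm = 8) extractCube(vol, sideMm)
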