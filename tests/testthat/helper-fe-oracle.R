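# Independent micro-FE oracle: dense assembly with its own 4x4x4
# Gauss-Legendre element matrix and mutual-energy homogenization
# (C_ij = U_i' K U_j / V with the full stiffness and full displacement
# vectors). Shares nothing with the package implementation beyond the
# node ordering convention, which is part of the element contract.

oracleElementK <- function(h, E, nu) {
  gp <- c(-0.8611363115940526, -0.3399810435848563,
          0.3399810435848563, 0.8611363115940526)
  gw <- c(0.3478548451374538, 0.6521451548625461,
          0.6521451548625461, 0.3478548451374538)
  nat <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(lam, 6, 6)
  D[4:6, ] <- 0; D[, 4:6] <- 0
  diag(D) <- c(rep(lam + 2 * mu, 3), rep(mu, 3))

  K <- matrix(0, 24, 24)
  for (ia in 1:4) for (ib in 1:4) for (ic in 1:4) {
    x <- gp[ia]; y <- gp[ib]; z <- gp[ic]
    B <- matrix(0, 6, 24)
    for (k in 1:8) {
      dx <- nat[k, 1] * (1 + y * nat[k, 2]) * (1 + z * nat[k, 3]) / 8 * 2 / h
      dy <- (1 + x * nat[k, 1]) * nat[k, 2] * (1 + z * nat[k, 3]) / 8 * 2 / h
      dz <- (1 + x * nat[k, 1]) * (1 + y * nat[k, 2]) * nat[k, 3] / 8 * 2 / h
      c0 <- 3 * (k - 1)
      B[1, c0 + 1] <- dx
      B[2, c0 + 2] <- dy
      B[3, c0 + 3] <- dz
      B[4, c0 + 1] <- dy; B[4, c0 + 2] <- dx
      B[5, c0 + 1] <- dz; B[5, c0 + 3] <- dx
      B[6, c0 + 2] <- dz; B[6, c0 + 3] <- dy
    }
    K <- K + t(B) %*% D %*% B * (h / 2)^3 * gw[ia] * gw[ib] * gw[ic]
  }
  K
}

# dense KUBC homogenization of a small occupancy array
oracleHomogenize <- function(occ, h, E = 12, nu = 0.3) {
  d <- dim(occ)
  Ke <- oracleElementK(h, E, nu)
  nxp <- d[1] + 1L; nyp <- d[2] + 1L; nzp <- d[3] + 1L
  nodeId <- array(seq_len(nxp * nyp * nzp), c(nxp, nyp, nzp))
  ndof <- 3L * length(nodeId)
  K <- matrix(0, ndof, ndof)
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!occ[i, j, k]) next
    ids <- integer(8)
    for (q in 1:8)
      ids[q] <- nodeId[i + offs[q, 1], j + offs[q, 2], k + offs[q, 3]]
    dofs <- as.vector(t(cbind(3 * ids - 2, 3 * ids - 1, 3 * ids)))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  # drop nodes untouched by any element
  used <- which(colSums(abs(K)) > 0 | rowSums(abs(K)) > 0)
  usedNodes <- sort(unique((used - 1) %/% 3 + 1))
  dofs <- as.vector(t(cbind(3 * usedNodes - 2, 3 * usedNodes - 1,
                            3 * usedNodes)))
  K <- K[dofs, dofs]
  ijk <- cbind((usedNodes - 1) %% nxp,
               ((usedNodes - 1) %/% nxp) %% nyp,
               (usedNodes - 1) %/% (nxp * nyp))
  coords <- ijk * h
  onBoundary <- ijk[, 1] == 0 | ijk[, 1] == d[1] |
                ijk[, 2] == 0 | ijk[, 2] == d[2] |
                ijk[, 3] == 0 | ijk[, 3] == d[3]
  fixedDof <- rep(onBoundary, each = 3)

  strains <- list()
  for (case in 1:6) {
    e <- matrix(0, 3, 3)
    if (case <= 3) e[case, case] <- 1
    else {
      ij <- list(c(1, 2), c(1, 3), c(2, 3))[[case - 3]]
      e[ij[1], ij[2]] <- e[ij[2], ij[1]] <- 0.5
    }
    strains[[case]] <- e
  }
  U <- matrix(0, nrow(K), 6)
  for (case in 1:6) {
    ub <- as.vector(t(coords %*% t(strains[[case]])))
    u <- ub
    free <- !fixedDof
    if (any(free)) {
      rhs <- -K[free, !free, drop = FALSE] %*% ub[!free]
      u[free] <- solve(K[free, free], rhs)
    }
    U[, case] <- u
  }
  V <- prod(d) * h^3
  C <- t(U) %*% K %*% U / V
  (C + t(C)) / 2
}
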