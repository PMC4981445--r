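# Constructed phantoms used across the suite. All are built in code at
# test time; voxel sizes in mm.

# thick connected two-intensity phantom: a plate and two beams, every
# component at least 3 voxels wide so interior seeds exist everywhere
designedPhantom <- function(boneIntensity = 1000, background = 0,
                            voxelMm = 0.05) {
  ph <- array(FALSE, c(32, 32, 32))
  ph[8:24, 8:12, 8:24] <- TRUE
  ph[10:14, 8:28, 10:14] <- TRUE
  ph[20:24, 8:28, 18:22] <- TRUE
  list(mask = ph,
       vol = GrayVolume(array(ifelse(ph, boneIntensity, background),
                              dim(ph)), voxelMm))
}

# straight interior rod along z
rodPhantom <- function(n = 9, voxelMm = 0.1) {
  a <- array(FALSE, c(n, n, n))
  a[(n + 1) %/% 2, (n + 1) %/% 2, 2:(n - 1)] <- TRUE
  BinaryVolume(a, voxelMm)
}

# three orthogonal rods crossing at the center voxel
crossPhantom <- function(n = 15, voxelMm = 0.1) {
  a <- array(FALSE, c(n, n, n))
  c0 <- (n + 1) %/% 2
  a[c0, c0, 3:(n - 2)] <- TRUE
  a[c0, 3:(n - 2), c0] <- TRUE
  a[3:(n - 2), c0, c0] <- TRUE
  BinaryVolume(a, voxelMm)
}

# H-shaped phantom: two vertical rods joined by a crossbar
hPhantom <- function(voxelMm = 0.1) {
  a <- array(FALSE, c(17, 17, 17))
  a[5, 9, 3:15] <- TRUE
  a[13, 9, 3:15] <- TRUE
  a[5:13, 9, 9] <- TRUE
  BinaryVolume(a, voxelMm)
}

# parallel slabs, symmetric about the volume so midplanes sit half a
# period from the faces: period 1.0 mm, thickness 0.2 mm at 0.02 mm
slabPhantom <- function(voxelMm = 0.02) {
  d <- 100L
  a <- array(FALSE, c(d, d, d))
  z <- rep(FALSE, d)
  z[21:30] <- TRUE
  z[71:80] <- TRUE
  a[, , z] <- TRUE
  BinaryVolume(a, voxelMm)
}

# small random porous mask guaranteed non-empty and reproducible
randomMask <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  a <- array(runif(n^3) < p, c(n, n, n))
  if (!any(a)) a[1, 1, 1] <- TRUE
  BinaryVolume(a, 0.05)
}
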