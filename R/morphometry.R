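## 3D histomorphometry: topology-preserving skeletonization, junction and
## free-end census, sphere-fitting local thickness, and the seven
## structure parameters.

# neighbour count (26-connectivity) for every voxel of a logical array
neighbourCount26 <- function(m) {
  cnt <- array(0L, dim(m))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    s <- m
    if (dx != 0) s <- shiftArray(s, 1L, dx, FALSE)
    if (dy != 0) s <- shiftArray(s, 2L, dy, FALSE)
    if (dz != 0) s <- shiftArray(s, 3L, dz, FALSE)
    cnt <- cnt + s
  }
  cnt
}

#' Skeletonize a binary volume to voxel-wide lines
#'
#' Topology-preserving 6-directional thinning based on the simple-point
#' characterization (a voxel is deletable iff removing it changes neither
#' the object's nor the background's local connectivity). With
#' `preserve = "curves"` free ends are retained and the result is a
#' voxel-wide curve skeleton; with `preserve = "surfaces"` width-1 plates
#' are retained and plate-like structures thin to their mid-surfaces.
#'
#' @param mask a non-empty [BinaryVolume-class].
#' @param preserve `"curves"` (default) or `"surfaces"`.
#' @return a [Skeleton-class] (census computed for the curve skeleton;
#'   see [countNodesTermini] for the counting rules).
#' @examples
#' rod <- array(FALSE, c(9, 9, 9)); rod[5, 5, 2:8] <- TRUE
#' skeletonize(BinaryVolume(rod, 0.1))
#' @export
skeletonize <- function(mask, preserve = c("curves", "surfaces")) {
  stopifnot(is(mask, "BinaryVolume"))
  preserve <- match.arg(preserve)
  if (!any(mask@voxels)) stop("cannot skeletonize an empty mask")
  d <- dim(mask)
  thin <- thin3dCpp(as.vector(mask@voxels), as.integer(d),
                    if (preserve == "curves") 0L else 1L)
  skel <- BinaryVolume(array(thin, d), voxelSize(mask))
  census <- skeletonCensus(skel)
  new("Skeleton", skeletonMask = skel, nNodes = census$nNodes,
      nTermini = census$nTermini, totalLengthMm = census$lengthMm)
}

# node/terminus/length census of a unit-width skeleton mask
skeletonCensus <- function(skel) {
  m <- skel@voxels
  d <- dim(m)
  h <- voxelSize(skel)
  cnt <- neighbourCount26(m)

  # termini: exactly one skeleton neighbour, excluding volume-border ends
  # (a trabecula cut by the field of view is not a free end)
  border <- array(FALSE, d)
  border[c(1L, d[1]), , ] <- TRUE
  border[, c(1L, d[2]), ] <- TRUE
  border[, , c(1L, d[3])] <- TRUE
  nTermini <- sum(m & cnt == 1L & !border)

  # junction clusters: voxels with >= 3 branches, merged 26-connectively
  # so one thick crossing counts once
  junction <- m & cnt >= 3L
  nNodes <- 0L
  if (any(junction)) {
    lab <- labelComponentsCpp(as.vector(junction), as.integer(d), 26L)
    nNodes <- max(lab)
  }

  # polyline length: each unique 26-adjacency link once
  lengthMm <- 0
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                   c(0, 1, 1), c(0, 1, -1),
                   c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))) {
    s <- m
    for (ax in 1:3) if (off[ax] != 0) s <- shiftArray(s, ax, off[ax], FALSE)
    lengthMm <- lengthMm + sum(m & s) * h * sqrt(sum(off^2))
  }
  list(nNodes = as.integer(nNodes), nTermini = as.integer(nTermini),
       lengthMm = lengthMm)
}

#' Junction and free-end densities of a skeleton
#'
#' Trabecular nodes: 26-connected clusters of skeleton voxels with at
#' least three branches, counted once per cluster. Trabecular termini:
#' skeleton voxels with exactly one neighbour, excluding ends on the
#' volume border.
#'
#' @param skel a [Skeleton-class].
#' @param volumeMm3 reference volume in mm^3 (> 0).
#' @return named numeric: `tbNd` (nodes/mm^3) and `tbTm` (termini/mm^3).
#' @export
countNodesTermini <- function(skel, volumeMm3) {
  stopifnot(is(skel, "Skeleton"), volumeMm3 > 0)
  c(tbNd = skel@nNodes / volumeMm3, tbTm = skel@nTermini / volumeMm3)
}

#' Sphere-fitting local thickness map
#'
#' For every foreground voxel, the diameter in mm of the largest
#' inscribed sphere containing it (Hildebrand-Ruegsegger model-independent
#' thickness). The sphere radius at a candidate center is its Euclidean
#' distance to the background minus half a voxel, so an isolated voxel
#' has thickness one voxel.
#'
#' @param mask a non-empty [BinaryVolume-class].
#' @return numeric 3D array of thickness values (mm); 0 outside the mask.
#' @export
localThickness <- function(mask) {
  stopifnot(is(mask, "BinaryVolume"))
  if (!any(mask@voxels)) stop("empty mask")
  d <- dim(mask)
  th <- localThicknessCpp(as.vector(mask@voxels), as.integer(d))
  array(th, d) * voxelSize(mask)
}

#' Compute the seven 3D structure parameters
#'
#' \describe{
#'   \item{BV/TV}{bone voxels / total voxels (exact integer ratio).}
#'   \item{Tb.Th}{mean sphere-fitting local thickness of the bone phase (mm).}
#'   \item{Tb.Sp}{mean local thickness of the marrow (background) phase (mm).}
#'   \item{Tb.Sc}{mean local thickness of the complement of the skeleton
#'     (mm): the distance between trabecular midlines. Computed against the
#'     mid-surface skeleton so plate-like structures measure the distance
#'     between their mid-planes.}
#'   \item{Tb.N}{1 / Tb.Sc (1/mm).}
#'   \item{Tb.Nd, Tb.Tm}{junction clusters and interior free ends of the
#'     curve skeleton per mm^3.}
#' }
#'
#' @param mask a [BinaryVolume-class] with at least one bone voxel and at
#'   least one background voxel (skeleton-based parameters are undefined
#'   for empty or full masks).
#' @return a [StructureMetrics-class].
#' @examples
#' truth <- generateGroundTruth(PhantomSpec(seed = 11))
#' computeMetrics(truth)
#' @export
computeMetrics <- function(mask) {
  stopifnot(is(mask, "BinaryVolume"))
  m <- mask@voxels
  frac <- sum(m) / length(m)
  if (frac == 0 || frac == 1)
    stop(sprintf(
      "mask is %s; BV/TV = %g but skeleton-based parameters are undefined",
      if (frac == 0) "empty" else "full", frac))
  h <- voxelSize(mask)
  d <- dim(m)
  totalMm3 <- prod(d) * h^3

  thBone <- localThickness(mask)
  tbTh <- mean(thBone[m])
  bg <- BinaryVolume(!m, h)
  thBg <- localThickness(bg)
  tbSp <- mean(thBg[!m])

  skelCurve <- skeletonize(mask, preserve = "curves")
  census <- countNodesTermini(skelCurve, totalMm3)

  skelSurf <- thin3dCpp(as.vector(m), as.integer(d), 1L)
  comp <- BinaryVolume(array(!skelSurf, d), h)
  thComp <- localThickness(comp)
  tbSc <- mean(thComp[comp@voxels])

  new("StructureMetrics", tbNd = unname(census["tbNd"]),
      tbTm = unname(census["tbTm"]), tbSp = tbSp, tbSc = tbSc,
      tbN = 1 / tbSc, tbTh = tbTh, bvtv = frac)
}
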