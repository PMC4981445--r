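## Synthetic trabecular phantoms and the scan simulator.
##
## Ground truth is a thresholded anisotropic Gaussian random field:
## white noise smoothed with a separable Gaussian kernel (applied in the
## frequency domain, periodic boundaries) and thresholded by bisection to
## the requested volume fraction. This produces connected plate/rod
## mixtures whose thickness tracks the smoothing length: for a field
## smoothed with sigma (in mm) and thresholded near BV/TV = 0.1, the mean
## chord length above threshold is close to 2*sigma, so thicknessScaleMm
## maps to Tb.Th ~ 2*thicknessScaleMm.

# separable Gaussian frequency response on the periodic grid
gaussianTransfer <- function(d, sigmaVox) {
  hs <- lapply(1:3, function(ax) {
    k <- seq_len(d[ax]) - 1L
    k[k > d[ax] / 2] <- k[k > d[ax] / 2] - d[ax]
    k <- k / d[ax]
    exp(-2 * pi^2 * sigmaVox[ax]^2 * k^2)
  })
  H <- outer(outer(hs[[1]], hs[[2]]), hs[[3]])
  dim(H) <- d
  H
}

smoothField <- function(a, sigmaVox) {
  if (all(sigmaVox <= 0)) return(a)
  H <- gaussianTransfer(dim(a), sigmaVox)
  Re(fft(fft(a) * H, inverse = TRUE)) / prod(dim(a))
}

#' Generate a ground-truth trabecular phantom
#'
#' Draws white noise on the phantom grid, smooths it with an anisotropic
#' Gaussian (correlation length `thicknessScaleMm` transversally, times
#' `anisotropy` along axis 3) and finds by bisection the threshold whose
#' excursion set has the target volume fraction.
#'
#' @param spec a [PhantomSpec-class].
#' @param tolerance admissible |BV/TV - target| (default 0.004, inside the
#'   contract bound of 0.005).
#' @return a [BinaryVolume-class] whose BV/TV is within `tolerance` of
#'   `targetBvtv`. Deterministic for a fixed spec (seed included).
#' @examples
#' truth <- generateGroundTruth(PhantomSpec(targetBvtv = 0.3, seed = 7))
#' bvtv(truth)
#' @export
generateGroundTruth <- function(spec, tolerance = 0.004) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- as.integer(round(spec@sideMm / spec@fineVoxelMm))
  sigmaT <- spec@thicknessScaleMm / spec@fineVoxelMm
  sigma <- c(sigmaT, sigmaT, sigmaT * spec@anisotropy)

  set.seed(spec@seed)
  noise <- array(rnorm(n^3), c(n, n, n))
  field <- smoothField(noise, sigma)

  lo <- min(field); hi <- max(field)
  thr <- NA_real_
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    frac <- mean(field > mid)
    if (abs(frac - spec@targetBvtv) <= tolerance) { thr <- mid; break }
    if (frac > spec@targetBvtv) lo <- mid else hi <- mid
  }
  if (is.na(thr))
    stop(sprintf(
      "bisection failed to reach BV/TV = %.3f (last fraction %.4f); the field may be too coarse for this target",
      spec@targetBvtv, frac))
  BinaryVolume(field > thr, spec@fineVoxelMm)
}

# integer-factor block-average resampling (detector integration)
blockAverage <- function(a, f) {
  if (f == 1L) return(a)
  d <- dim(a) %/% f * f
  a <- a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  nd <- d %/% f
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  a <- aperm(a, c(2, 4, 6, 1, 3, 5))
  dim(a) <- c(prod(nd), f^3)
  array(rowMeans(a), nd)
}

#' Simulate a clinical-resolution rescan of a ground-truth structure
#'
#' Assigns bone/background intensities (with spatially correlated
#' intra-bone heterogeneity emulating mineralization spread and the
#' shading of uncalibrated cone-beam intensities), blurs with a Gaussian
#' PSF, block-averages down to the requested voxel size (integer factor
#' of the source voxel) and adds Gaussian noise. The order (blur, then
#' integrate, then noise) mimics detector integration of an optically
#' blurred signal.
#'
#' @param truth a [BinaryVolume-class] ground truth.
#' @param imaging an [ImagingSpec-class].
#' @return a [GrayVolume-class] at the realized voxel size
#'   (`round(outVoxelMm / voxelSize(truth))` source voxels per output
#'   voxel).
#' @examples
#' truth <- generateGroundTruth(PhantomSpec(seed = 3))
#' scan <- simulateScan(truth, ImagingSpec(outVoxelMm = 0.15, seed = 3))
#' @export
simulateScan <- function(truth, imaging) {
  stopifnot(is(truth, "BinaryVolume"), is(imaging, "ImagingSpec"))
  validObject(imaging)
  h <- voxelSize(truth)
  if (h > imaging@outVoxelMm + 1e-12)
    stop("source voxel is larger than the requested output voxel")
  f <- max(1L, as.integer(round(imaging@outVoxelMm / h)))

  set.seed(imaging@seed)
  boneSignal <- array(imaging@boneIntensity, dim = dim(truth))
  if (imaging@boneHeterogeneitySd > 0) {
    het <- array(rnorm(length(truth@voxels)), dim = dim(truth))
    het <- smoothField(het, rep(0.2 / h, 3))
    het <- het / sd(het) * imaging@boneHeterogeneitySd
    boneSignal <- boneSignal + het
  }
  img <- imaging@backgroundIntensity +
    (boneSignal - imaging@backgroundIntensity) *
      array(as.numeric(truth@voxels), dim = dim(truth))
  if (imaging@psfFwhmMm > 0) {
    sigmaVox <- imaging@psfFwhmMm / 2.35482 / h
    img <- smoothField(img, rep(sigmaVox, 3))
  }
  img <- blockAverage(img, f)
  if (imaging@noiseSd > 0)
    img <- img + array(rnorm(length(img), sd = imaging@noiseSd), dim = dim(img))
  GrayVolume(img, f * h)
}

#' Generate a full specimen set: truths plus multi-modality rescans
#'
#' Builds `n` phantoms whose target volume fractions increase over the
#' trabecular range 0.05-0.45, and for each one a fine (micro-CT grade)
#' rescan plus a set of degraded clinical-resolution rescans. All seeds
#' derive from `baseSeed`; the design is fully reproducible.
#'
#' @param n number of specimens (>= 3).
#' @param baseSeed master seed.
#' @param phantom template [PhantomSpec-class]; `targetBvtv` and `seed`
#'   are overridden per specimen.
#' @param fineImaging [ImagingSpec-class] for the micro-CT-grade rescan;
#'   defaults to the source voxel size with mild blur and CNR = 20.
#' @param clinicalImaging named list of [ImagingSpec-class] for degraded
#'   rescans; default two modalities (CNR about 8 and 6) plus a repeat of
#'   the first for reproducibility analysis.
#' @param bvtvRange range of target volume fractions (default c(0.05, 0.45)).
#' @return a list of specimens; each has `id`, `spec`, `truth`,
#'   `scans` (named list of [GrayVolume-class], first element `fine`) and
#'   `imaging` (the specs used).
#' @export
makeSpecimenSet <- function(n = 14L, baseSeed = 20160811L,
                            phantom = PhantomSpec(),
                            fineImaging = NULL, clinicalImaging = NULL,
                            bvtvRange = c(0.05, 0.45)) {
  stopifnot(n >= 3)
  h <- phantom@fineVoxelMm
  if (is.null(fineImaging))
    fineImaging <- ImagingSpec(outVoxelMm = h, psfFwhmMm = 1.2 * h,
                               noiseSd = 50, boneIntensity = 1000,
                               backgroundIntensity = 0,
                               boneHeterogeneitySd = 100)
  if (is.null(clinicalImaging))
    clinicalImaging <- list(
      cbct_a = ImagingSpec(outVoxelMm = 0.15, psfFwhmMm = 0.20, noiseSd = 80),
      cbct_a_repeat = ImagingSpec(outVoxelMm = 0.15, psfFwhmMm = 0.20,
                                  noiseSd = 80),
      cbct_n = ImagingSpec(outVoxelMm = 0.20, psfFwhmMm = 0.25, noiseSd = 105))

  set.seed(baseSeed)
  nScans <- 1L + length(clinicalImaging)
  seedPool <- matrix(sample.int(.Machine$integer.max - 1L, n * (nScans + 1L)),
                     nrow = n)
  targets <- seq(bvtvRange[1], bvtvRange[2], length.out = n)

  lapply(seq_len(n), function(i) {
    spec <- phantom
    spec@targetBvtv <- targets[i]
    spec@seed <- seedPool[i, 1L]
    truth <- generateGroundTruth(spec)
    specs <- c(list(fine = fineImaging), clinicalImaging)
    scans <- vector("list", length(specs))
    names(scans) <- names(specs)
    for (s in seq_along(specs)) {
      sp <- specs[[s]]
      sp@seed <- seedPool[i, 1L + s]
      specs[[s]] <- sp
      scans[[s]] <- simulateScan(truth, sp)
    }
    list(id = sprintf("S%02d", i), spec = spec, truth = truth,
         scans = scans, imaging = specs)
  })
}

#' Write a specimen manifest as CSV
#'
#' @param specimens result of [makeSpecimenSet].
#' @param path output CSV path.
#' @return the manifest data.frame, invisibly.
#' @export
writeSpecimenManifest <- function(specimens, path) {
  man <- do.call(rbind, lapply(specimens, function(s) {
    data.frame(specimen_id = s$id, seed = s$spec@seed,
               target_bvtv = s$spec@targetBvtv,
               realized_bvtv = bvtv(s$truth),
               fine_voxel_mm = voxelSize(s$truth),
               scans = paste(names(s$scans), collapse = ";"))
  }))
  write.csv(man, path, row.names = FALSE)
  invisible(man)
}
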