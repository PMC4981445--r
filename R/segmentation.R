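## Segmentation: automated region growing (ARG) over a schedule of
## homogeneity thresholds for clinical-resolution data, a histogram
## (Otsu) threshold for micro-CT-grade data, and CNR measurement.

# noise SD from axial second differences (pseudo-residuals): locally
# linear image structure cancels, white noise survives with SD sqrt(6)
# times sigma; the median of |residuals| makes the estimate robust to
# the remaining structure
pseudoResidualNoiseSd <- function(v) {
  d <- dim(v)[1]
  r <- as.vector(v[3:d, , , drop = FALSE] -
                 2 * v[2:(d - 1), , , drop = FALSE] +
                 v[1:(d - 2), , , drop = FALSE])
  1.4826 * median(abs(r)) / sqrt(6)
}

# shift a 3D array by one voxel along an axis, filling with `fill`
shiftArray <- function(a, ax, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[ax]
  if (n <= 1L) return(out)
  srcIdx <- dstIdx <- lapply(d, seq_len)
  if (by == 1L) { dstIdx[[ax]] <- 2:n; srcIdx[[ax]] <- 1:(n - 1L) }
  else { dstIdx[[ax]] <- 1:(n - 1L); srcIdx[[ax]] <- 2:n }
  out <- do.call(`[<-`, c(list(out), dstIdx,
                          list(do.call(`[`, c(list(a), srcIdx, list(drop = FALSE))))))
  out
}

#' Select seed voxels for region growing
#'
#' Seeds are selected from the attenuation-value distribution of the
#' whole volume. By default (`seedPercentile = NA`) the seed threshold is
#' the larger of the between-class-variance (Otsu) split and a
#' background-outlier bound (histogram mode plus four robust background
#' SDs, estimated from the left half of the dominant mode, which bone --
#' always brighter -- cannot contaminate), capped at the 99.5th
#' percentile so the seed set is never empty. The Otsu bound makes the
#' seeds span the bone intensity class on well-separated histograms; the
#' outlier bound protects against near-unimodal histograms at low bone
#' fraction, where the Otsu split falls inside the noise. With a numeric
#' `seedPercentile`, the voxels above that percentile are used instead.
#' The set is then eroded by one voxel (6-connectivity) to interior
#' voxels; if erosion leaves fewer than two voxels (possible at coarse
#' resolution) the un-eroded set is used.
#'
#' @param vol a [GrayVolume-class].
#' @param config an [ARGConfig-class].
#' @return a [BinaryVolume-class] seed mask.
#' @export
selectSeeds <- function(vol, config = ARGConfig()) {
  stopifnot(is(vol, "GrayVolume"))
  v <- vol@voxels
  if (diff(range(v)) == 0)
    stop("volume is constant; cannot select seeds")
  if (is.na(config@seedPercentile)) {
    x <- as.vector(v)
    thrOtsu <- otsuThreshold(x)
    noise <- pseudoResidualNoiseSd(v)
    sepOk <- noise > 0 &&
      (mean(x[x > thrOtsu]) - mean(x[x <= thrOtsu])) >= 3 * noise
    q <- if (sepOk) {
      thrOtsu
    } else {
      # near-unimodal histogram (low bone fraction): the histogram split
      # falls inside the noise; use a background-outlier bound instead
      br <- seq(min(x), max(x), length.out = 513)
      cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                      nbins = 512)
      mode <- ((br[-1] + br[-513]) / 2)[which.max(cnt)]
      mode + 4 * noise
    }
    q <- min(q, quantile(x, 0.995, names = FALSE))
    m <- v >= q
  } else {
    q <- quantile(v, config@seedPercentile / 100, names = FALSE)
    m <- v >= q
    if (!any(m))
      stop("seed set empty; lower seedPercentile")
    er <- m
    for (ax in 1:3) for (by in c(1L, -1L))
      er <- er & shiftArray(m, ax, by, fill = FALSE)
    if (sum(er) < 2) {
      # at coarse resolution no percentile voxel may survive erosion;
      # fall back to the un-eroded high-intensity tail
      message("seed erosion left <2 voxels; using the un-eroded tail")
      er <- m
    }
    m <- er
  }
  BinaryVolume(m, voxelSize(vol))
}

#' Strictest homogeneity threshold: the spread of the seed intensities
#'
#' The standard deviation of the intensities in the seed mask. A zero
#' spread (uniform seeds) is floored to a small epsilon relative to the
#' volume's intensity range so the threshold schedule stays usable.
#'
#' @param vol a [GrayVolume-class].
#' @param seeds a [BinaryVolume-class] seed mask.
#' @return positive scalar homogeneity threshold.
#' @export
strictestThreshold <- function(vol, seeds) {
  stopifnot(is(vol, "GrayVolume"), is(seeds, "BinaryVolume"))
  vals <- vol@voxels[seeds@voxels]
  if (length(vals) == 0) stop("empty seed set")
  s <- if (length(vals) > 1) sd(vals) else 0
  if (!is.finite(s) || s == 0) {
    eps <- max(diff(range(vol@voxels)) * 1e-6, .Machine$double.eps)
    message("seed spread is zero; flooring the strictest threshold to ", eps)
    s <- eps
  }
  s
}

#' Grow a region from seeds under a homogeneity threshold
#'
#' Face-connected (6-neighbour) region growth. With
#' `reference = "seed"` (the default, used by [argSegment]) a voxel is
#' admissible when its intensity does not fall more than `threshold`
#' below the seed mean (one-sided: bone is the bright phase, so voxels
#' brighter than the seeds are never background); the result is the
#' union of admissible connected components containing seeds. This rule
#' is monotone in `threshold` (larger thresholds give supersets), and
#' idempotent given the same reference mean. With
#' `reference = "running"` a voxel is admitted when it deviates from the
#' running region mean by at most `threshold` (two-sided), evaluated in
#' synchronous sweeps so the result does not depend on voxel enumeration
#' order; the fixed point is idempotent but the running mean can drift
#' along partial-volume intensity continua.
#'
#' @param vol a [GrayVolume-class].
#' @param seeds a [BinaryVolume-class]; must be non-empty.
#' @param threshold homogeneity threshold (>= 0; `Inf` floods the whole
#'   connected volume).
#' @param reference `"seed"` or `"running"`.
#' @param referenceMean optional numeric overriding the seed mean (used
#'   to regrow reproducibly from a previous result).
#' @return a [BinaryVolume-class] containing the seeds.
#' @export
regionGrow <- function(vol, seeds, threshold,
                       reference = c("seed", "running"),
                       referenceMean = NULL) {
  stopifnot(is(vol, "GrayVolume"), is(seeds, "BinaryVolume"), threshold >= 0)
  reference <- match.arg(reference)
  d <- dim(vol)
  if (!any(seeds@voxels)) stop("empty seed set")
  if (reference == "running") {
    grown <- regionGrowCpp(as.vector(vol@voxels), as.vector(seeds@voxels),
                           threshold, as.integer(d))
    return(BinaryVolume(array(grown, d), voxelSize(vol)))
  }
  mu <- if (is.null(referenceMean)) mean(vol@voxels[seeds@voxels])
        else referenceMean
  adm <- seeds@voxels | (vol@voxels >= mu - threshold)
  lab <- labelComponentsCpp(as.vector(adm), as.integer(d), 6L)
  keep <- unique(lab[as.vector(seeds@voxels)])
  grown <- array(lab %in% keep[keep > 0] & lab > 0, d)
  BinaryVolume(grown, voxelSize(vol))
}

#' Assessment function scoring a candidate segmentation
#'
#' `w1 * log(WCV) - w2 * log(G2)`, where WCV is the pooled within-class
#' variance of the mask partition, `(n_in var_in + n_out var_out) / n`,
#' and G2 the mean squared intensity jump across the mask boundary
#' (6-neighbour face pairs). The within-class term penalizes both
#' over-segmentation (a region that swallows background becomes
#' inhomogeneous) and under-segmentation (bone left outside inflates the
#' residual-background variance); the boundary-gradient term rejects
#' masks whose boundary runs through a single phase -- in particular
#' background floods, whose boundaries carry only noise-level contrast.
#' Lower is better. On a noise-free two-intensity phantom the true mask
#' scores `-Inf` (WCV = 0), strictly below any dilated or eroded variant.
#'
#' @param vol a [GrayVolume-class].
#' @param mask a [BinaryVolume-class]; must be neither empty nor full
#'   (score is `+Inf` otherwise).
#' @param weights length-2 non-negative weights (within-class variance,
#'   boundary gradient).
#' @return scalar score (lower is better).
#' @export
assessment <- function(vol, mask, weights = c(1, 1)) {
  stopifnot(is(vol, "GrayVolume"), is(mask, "BinaryVolume"))
  m <- mask@voxels
  if (!any(m) || all(m)) return(Inf)
  v <- vol@voxels
  n <- length(v)
  nin <- sum(m)
  varIn <- if (nin > 1) var(v[m]) else 0
  varOut <- if (n - nin > 1) var(v[!m]) else 0
  wcv <- (nin / n) * varIn + ((n - nin) / n) * varOut

  gsum <- 0; gcount <- 0
  for (ax in 1:3) for (by in c(1L, -1L)) {
    nb <- shiftArray(m, ax, by, fill = NA)
    vb <- shiftArray(v, ax, by, fill = NA_real_)
    sel <- m & !is.na(nb) & !nb     # in-region voxels facing out-region
    if (any(sel)) {
      gsum <- gsum + sum((v[sel] - vb[sel])^2)
      gcount <- gcount + sum(sel)
    }
  }
  grad2 <- if (gcount > 0) gsum / gcount else 0

  if (wcv == 0) return(-Inf)       # perfect two-class split
  if (grad2 == 0) return(Inf)      # boundary entirely inside one phase
  weights[1] * log(wcv) - weights[2] * log(grad2)
}

#' Automated region growing segmentation
#'
#' Runs region growth over a schedule of homogeneity thresholds linearly
#' spaced from the strictest (the seed-intensity spread) to
#' `permissiveFactor` times it, inclusive, scores each candidate mask
#' with the [assessment] function and selects the minimum (ties resolved
#' to the strictest iteration). Each iteration regrows from the original
#' seeds with the seed-mean reference, so the mask sequence is monotone
#' nested by construction: the strict end under-segments, the permissive
#' end clearly over-segments, and the assessment minimum sits between.
#'
#' @param vol a [GrayVolume-class].
#' @param config an [ARGConfig-class].
#' @return an [ARGResult-class]. The `masksNested` flag records whether
#'   the mask sequence was monotone non-decreasing over the schedule
#'   (always true for the seed-reference growth rule; retained as a
#'   recorded invariant).
#' @examples
#' truth <- generateGroundTruth(PhantomSpec(seed = 5))
#' scan <- simulateScan(truth, ImagingSpec(seed = 5))
#' res <- argSegment(scan)
#' res
#' @export
argSegment <- function(vol, config = ARGConfig()) {
  stopifnot(is(vol, "GrayVolume"), is(config, "ARGConfig"))
  validObject(config)
  seeds <- selectSeeds(vol, config)
  t0 <- strictestThreshold(vol, seeds)
  thresholds <- seq(t0, config@permissiveFactor * t0,
                    length.out = config@nIterations)

  mu <- mean(vol@voxels[seeds@voxels])
  scores <- numeric(config@nIterations)
  nested <- TRUE
  prev <- NULL
  best <- NULL; bestScore <- Inf; bestIter <- 1L
  for (k in seq_len(config@nIterations)) {
    mk <- regionGrow(vol, seeds, thresholds[k], reference = "seed",
                     referenceMean = mu)
    g <- mk@voxels
    if (!is.null(prev) && any(prev & !g)) nested <- FALSE
    scores[k] <- assessment(vol, mk, config@assessmentWeights)
    if (scores[k] < bestScore) { bestScore <- scores[k]; best <- mk; bestIter <- k }
    prev <- g
  }
  new("ARGResult", selectedMask = best, selectedIteration = bestIter,
      thresholds = thresholds, assessmentValues = scores,
      masksNested = nested)
}

#' Histogram (Otsu) threshold segmentation
#'
#' Global threshold maximizing the between-class variance of the
#' intensity histogram; the upper class is bone. Intended for
#' calibrated, high-CNR micro-CT-grade data.
#'
#' @param vol a [GrayVolume-class] with more than one distinct intensity.
#' @param nbins number of histogram bins used when the volume has many
#'   distinct values (exact scan over unique values is used when there
#'   are fewer than `nbins`).
#' @return a [BinaryVolume-class].
#' @export
otsuSegment <- function(vol, nbins = 1024L) {
  stopifnot(is(vol, "GrayVolume"))
  thr <- otsuThreshold(as.vector(vol@voxels), nbins)
  BinaryVolume(vol@voxels > thr, voxelSize(vol))
}

# between-class-variance-maximizing threshold; exact scan over unique
# values when few, histogram bins otherwise
otsuThreshold <- function(v, nbins = 1024L) {
  u <- sort(unique(v))
  if (length(u) < 2) stop("volume is constant; cannot threshold")
  if (length(u) <= nbins) {
    centers <- u
    counts <- tabulate(match(v, u), nbins = length(u))
  } else {
    br <- seq(min(v), max(v), length.out = nbins + 1L)
    cut <- findInterval(v, br, rightmost.closed = TRUE)
    counts <- tabulate(cut, nbins = nbins)
    centers <- (br[-1] + br[-length(br)]) / 2
  }
  w <- counts / sum(counts)
  omega0 <- cumsum(w)
  mu0cum <- cumsum(w * centers)
  muT <- mu0cum[length(mu0cum)]
  omega1 <- 1 - omega0
  valid <- omega0 > 0 & omega1 > 0
  sigmaB <- rep(-Inf, length(w))
  sigmaB[valid] <- (muT * omega0[valid] - mu0cum[valid])^2 /
    (omega0[valid] * omega1[valid])
  kstar <- which.max(sigmaB)
  if (kstar < length(centers))
    (centers[kstar] + centers[kstar + 1]) / 2
  else centers[kstar]
}

#' Contrast-to-noise ratio between two regions of interest
#'
#' `|mean(bone) - mean(background)| / sd(background)`.
#'
#' @param vol a [GrayVolume-class].
#' @param boneRoi,backgroundRoi disjoint non-empty [BinaryVolume-class]
#'   regions of interest.
#' @return scalar CNR; `Inf` with a warning when the background SD is 0.
#' @export
cnr <- function(vol, boneRoi, backgroundRoi) {
  stopifnot(is(vol, "GrayVolume"))
  b <- vol@voxels[boneRoi@voxels]
  g <- vol@voxels[backgroundRoi@voxels]
  if (length(b) == 0 || length(g) == 0) stop("ROIs must be non-empty")
  if (any(boneRoi@voxels & backgroundRoi@voxels)) stop("ROIs must be disjoint")
  sdg <- sd(g)
  contrast <- abs(mean(b) - mean(g))
  if (!is.finite(sdg) || sdg == 0) {
    if (contrast == 0) return(0)
    warning("zero background SD; CNR is infinite")
    return(Inf)
  }
  contrast / sdg
}
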