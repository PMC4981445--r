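## S4 class definitions. Volumes are dense 3D arrays with an isotropic
## physical voxel size in mm; everything downstream (thickness maps, FE
## element edges, skeleton lengths) inherits its physical scale from it.

setClass("VoxelVolume",
  representation("VIRTUAL", voxels = "array", voxelSize = "numeric"))

setValidity("VoxelVolume", function(object) {
  msg <- NULL
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number (mm)")
  if (is.null(msg)) TRUE else msg
})

#' GrayVolume: a 3D gray-scale image volume
#'
#' A dense 3D scalar field (arbitrary intensity units) with an isotropic
#' voxel size in mm. The raw input to segmentation.
#'
#' @slot voxels numeric 3D array of intensities.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @export
setClass("GrayVolume", contains = "VoxelVolume")

setValidity("GrayVolume", function(object) {
  if (!is.numeric(object@voxels)) "voxels must be numeric" else TRUE
})

#' BinaryVolume: a bone mask
#'
#' A 3D logical array (TRUE = bone) with an isotropic voxel size in mm.
#' Output of segmentation, input to histomorphometry and micro-FE.
#'
#' @slot voxels logical 3D array.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @export
setClass("BinaryVolume", contains = "VoxelVolume")

setValidity("BinaryVolume", function(object) {
  if (!is.logical(object@voxels)) "voxels must be logical" else TRUE
})

#' @describeIn GrayVolume-class constructor.
#' @param voxels numeric 3D array.
#' @param voxelSize voxel edge length in mm.
#' @export
GrayVolume <- function(voxels, voxelSize) {
  storage.mode(voxels) <- "double"
  new("GrayVolume", voxels = voxels, voxelSize = as.numeric(voxelSize))
}

#' @describeIn BinaryVolume-class constructor. Accepts logical or 0/1
#'   numeric arrays.
#' @param voxels logical (or 0/1 numeric) 3D array.
#' @param voxelSize voxel edge length in mm.
#' @export
BinaryVolume <- function(voxels, voxelSize) {
  if (!is.logical(voxels)) {
    v <- array(as.logical(voxels != 0), dim = dim(voxels))
    voxels <- v
  }
  new("BinaryVolume", voxels = voxels, voxelSize = as.numeric(voxelSize))
}

#' PhantomSpec: ground-truth phantom parameters
#'
#' Parameters of a synthetic trabecular structure: a thresholded
#' anisotropic Gaussian random field on a cubic grid.
#'
#' @slot sideMm physical cube side (mm).
#' @slot fineVoxelMm ground-truth voxel size (mm).
#' @slot targetBvtv target bone volume fraction, in (0.02, 0.8).
#' @slot thicknessScaleMm correlation length controlling trabecular
#'   thickness (mm); mean Tb.Th is approximately twice this value.
#' @slot anisotropy ratio >= 1 of the axis-3 correlation length to the
#'   transverse one; values > 1 make the structure stiffer along axis 3.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec", representation(
  sideMm = "numeric", fineVoxelMm = "numeric", targetBvtv = "numeric",
  thicknessScaleMm = "numeric", anisotropy = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  ngrid <- object@sideMm / object@fineVoxelMm
  if (abs(ngrid - round(ngrid)) > 1e-8)
    msg <- c(msg, "sideMm / fineVoxelMm must be an integer grid dimension")
  if (round(ngrid) < 32)
    msg <- c(msg, "grid dimension must be >= 32")
  if (object@targetBvtv <= 0.02 || object@targetBvtv >= 0.8)
    msg <- c(msg, "targetBvtv must lie in (0.02, 0.8)")
  if (object@thicknessScaleMm <= 0)
    msg <- c(msg, "thicknessScaleMm must be positive")
  if (object@anisotropy < 1)
    msg <- c(msg, "anisotropy must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn PhantomSpec-class constructor with defaults. The default
#'   geometry is a scaled analysis cube (4.8 mm at 0.05 mm voxels, a 96^3
#'   grid) that preserves the ~8:5.3 ratio between analysis and FE cubes
#'   and the ~3-4x clinical-to-fine voxel ratio of the emulated study
#'   design while staying tractable on one CPU.
#' @param sideMm,fineVoxelMm,targetBvtv,thicknessScaleMm,anisotropy,seed
#'   see slots.
#' @export
PhantomSpec <- function(sideMm = 4.8, fineVoxelMm = 0.05, targetBvtv = 0.2,
                        thicknessScaleMm = 0.12, anisotropy = 1.4,
                        seed = 1L) {
  new("PhantomSpec", sideMm = sideMm, fineVoxelMm = fineVoxelMm,
      targetBvtv = targetBvtv, thicknessScaleMm = thicknessScaleMm,
      anisotropy = anisotropy, seed = as.integer(seed))
}

#' ImagingSpec: clinical rescan simulator parameters
#'
#' Describes degraded re-imaging of a ground-truth structure: a Gaussian
#' point-spread function, block-average detector integration down to a
#' coarser voxel and additive Gaussian noise on uncalibrated intensities.
#'
#' @slot outVoxelMm requested output voxel size (mm); realized as the
#'   nearest integer multiple of the source voxel.
#' @slot psfFwhmMm Gaussian PSF full width at half maximum (mm).
#' @slot noiseSd additive noise SD in intensity units.
#' @slot boneIntensity,backgroundIntensity mean intensities of bone/water.
#' @slot boneHeterogeneitySd SD of the spatially correlated (0.2 mm
#'   correlation length) intra-bone intensity variation, modeling tissue
#'   mineralization spread and the shading of uncalibrated cone-beam
#'   intensities; 0 disables it.
#' @slot seed integer RNG seed for the noise/heterogeneity streams.
#' @export
setClass("ImagingSpec", representation(
  outVoxelMm = "numeric", psfFwhmMm = "numeric", noiseSd = "numeric",
  boneIntensity = "numeric", backgroundIntensity = "numeric",
  boneHeterogeneitySd = "numeric", seed = "integer"))

setValidity("ImagingSpec", function(object) {
  msg <- NULL
  if (object@psfFwhmMm < 0) msg <- c(msg, "psfFwhmMm must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@boneHeterogeneitySd < 0)
    msg <- c(msg, "boneHeterogeneitySd must be >= 0")
  if (object@outVoxelMm <= 0) msg <- c(msg, "outVoxelMm must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ImagingSpec-class constructor. Defaults emulate a
#'   clinical-resolution scan: 0.15 mm voxels, 0.2 mm PSF and a noise
#'   level calibrated so the measured contrast-to-noise ratio (pure-phase
#'   ROI contrast over background SD) lands around 8, inside the 6-10
#'   range typical of the emulated devices.
#' @param outVoxelMm,psfFwhmMm,noiseSd,boneIntensity,backgroundIntensity,seed
#'   see slots.
#' @export
ImagingSpec <- function(outVoxelMm = 0.15, psfFwhmMm = 0.2, noiseSd = 80,
                        boneIntensity = 1000, backgroundIntensity = 0,
                        boneHeterogeneitySd = 200, seed = 1L) {
  new("ImagingSpec", outVoxelMm = outVoxelMm, psfFwhmMm = psfFwhmMm,
      noiseSd = noiseSd, boneIntensity = boneIntensity,
      backgroundIntensity = backgroundIntensity,
      boneHeterogeneitySd = boneHeterogeneitySd, seed = as.integer(seed))
}

#' ARGConfig: automated region growing configuration
#'
#' @slot nIterations number of homogeneity thresholds tried (default 50).
#' @slot permissiveFactor most permissive threshold as a multiple of the
#'   strictest (default 1.6).
#' @slot seedPercentile upper intensity percentile for seed selection;
#'   `NA` (the default) selects the upper class of the histogram
#'   (between-class variance) split instead of a fixed percentile.
#' @slot assessmentWeights length-2 weights (inhomogeneity, boundary
#'   gradient) of the assessment function.
#' @export
setClass("ARGConfig", representation(
  nIterations = "integer", permissiveFactor = "numeric",
  seedPercentile = "numeric", assessmentWeights = "numeric"))

setValidity("ARGConfig", function(object) {
  msg <- NULL
  if (object@nIterations < 2L) msg <- c(msg, "nIterations must be >= 2")
  if (object@permissiveFactor <= 1) msg <- c(msg, "permissiveFactor must be > 1")
  if (!is.na(object@seedPercentile) &&
      (object@seedPercentile <= 0 || object@seedPercentile >= 100))
    msg <- c(msg, "seedPercentile must be NA or in (0, 100)")
  if (length(object@assessmentWeights) != 2L ||
      any(object@assessmentWeights < 0))
    msg <- c(msg, "assessmentWeights must be two non-negative numbers")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ARGConfig-class constructor.
#' @param nIterations,permissiveFactor,seedPercentile,assessmentWeights
#'   see slots.
#' @export
ARGConfig <- function(nIterations = 50L, permissiveFactor = 1.6,
                      seedPercentile = NA_real_,
                      assessmentWeights = c(1, 1)) {
  new("ARGConfig", nIterations = as.integer(nIterations),
      permissiveFactor = permissiveFactor, seedPercentile = seedPercentile,
      assessmentWeights = as.numeric(assessmentWeights))
}

#' ARGResult: outcome of automated region growing segmentation
#'
#' @slot selectedMask the mask at the assessment-function minimum.
#' @slot selectedIteration 1-based index of the selected iteration.
#' @slot thresholds the homogeneity threshold schedule.
#' @slot assessmentValues assessment score per iteration (lower is better).
#' @slot masksNested TRUE if the mask sequence was non-decreasing.
#' @export
setClass("ARGResult", representation(
  selectedMask = "BinaryVolume", selectedIteration = "integer",
  thresholds = "numeric", assessmentValues = "numeric",
  masksNested = "logical"))

#' Skeleton: voxel-wide curve skeleton with census
#'
#' @slot skeletonMask unit-width skeleton as a [BinaryVolume-class].
#' @slot nNodes number of junction clusters (>= 3 branches).
#' @slot nTermini number of interior free ends.
#' @slot totalLengthMm summed length of skeleton adjacency links (mm).
#' @export
setClass("Skeleton", representation(
  skeletonMask = "BinaryVolume", nNodes = "integer", nTermini = "integer",
  totalLengthMm = "numeric"))

#' StructureMetrics: the seven 3D histomorphometric parameters
#'
#' @slot tbNd trabecular nodes per mm^3.
#' @slot tbTm trabecular termini per mm^3.
#' @slot tbSp trabecular separation (mm): mean local thickness of marrow.
#' @slot tbSc trabecular spacing (mm): mean distance between midlines.
#' @slot tbN trabecular number (1/mm), 1/Tb.Sc.
#' @slot tbTh trabecular thickness (mm): mean local thickness of bone.
#' @slot bvtv bone volume over total volume (fraction).
#' @export
setClass("StructureMetrics", representation(
  tbNd = "numeric", tbTm = "numeric", tbSp = "numeric", tbSc = "numeric",
  tbN = "numeric", tbTh = "numeric", bvtv = "numeric"))

#' FEModel: voxel hexahedral micro-FE model
#'
#' @slot occupancy bone-voxel occupancy after largest-component filtering.
#' @slot tissueE tissue Young's modulus (GPa), default 12.
#' @slot tissueNu tissue Poisson ratio, default 0.3.
#' @slot removedFraction fraction of bone voxels dropped when retaining
#'   the largest face-connected component.
#' @export
setClass("FEModel", representation(
  occupancy = "BinaryVolume", tissueE = "numeric", tissueNu = "numeric",
  removedFraction = "numeric"))

setValidity("FEModel", function(object) {
  msg <- NULL
  if (object@tissueE <= 0) msg <- c(msg, "tissueE must be positive")
  if (object@tissueNu < 0 || object@tissueNu >= 0.5)
    msg <- c(msg, "tissueNu must be in [0, 0.5)")
  if (!any(object@occupancy@voxels)) msg <- c(msg, "occupancy is empty")
  if (is.null(msg)) TRUE else msg
})

#' StiffnessResult: apparent elastic constants from homogenization
#'
#' Voigt ordering is (11, 22, 33, 12, 13, 23) with engineering shear
#' strains. Young's moduli are reported sorted so that E3 is the maximum;
#' Gmin is the smallest of the three shear moduli.
#'
#' @slot C 6x6 apparent stiffness matrix (GPa).
#' @slot E length-3 Young's moduli (GPa), ascending (E3 = max).
#' @slot G length-3 shear moduli G12, G13, G23 (GPa).
#' @slot Gmin minimum shear modulus (GPa).
#' @slot asymmetry max relative asymmetry of C before symmetrization.
#' @export
setClass("StiffnessResult", representation(
  C = "matrix", E = "numeric", G = "numeric", Gmin = "numeric",
  asymmetry = "numeric"))
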