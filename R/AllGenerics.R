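## Generics, accessors and show methods.

#' Voxel data of a volume
#' @param x a [GrayVolume-class] or [BinaryVolume-class].
#' @return the 3D array of voxel values.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@voxels)

#' Voxel size in mm
#' @param x a [GrayVolume-class] or [BinaryVolume-class].
#' @return isotropic voxel edge length in mm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VoxelVolume", function(x) x@voxelSize)

#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@voxels))

#' Bone volume fraction of a mask
#'
#' Exact integer ratio of bone voxels to total voxels.
#' @param x a [BinaryVolume-class] (or a [StructureMetrics-class], whose
#'   stored value is returned).
#' @return BV/TV as a fraction in [0, 1].
#' @export
setGeneric("bvtv", function(x) standardGeneric("bvtv"))

#' @rdname bvtv
#' @export
setMethod("bvtv", "BinaryVolume", function(x) sum(x@voxels) / length(x@voxels))

#' @rdname bvtv
#' @export
setMethod("bvtv", "StructureMetrics", function(x) x@bvtv)

setMethod("show", "GrayVolume", function(object) {
  d <- dim(object)
  r <- range(object@voxels)
  cat(sprintf("GrayVolume %dx%dx%d @ %.4g mm/voxel, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@voxelSize, r[1], r[2]))
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object)
  cat(sprintf("BinaryVolume %dx%dx%d @ %.4g mm/voxel, BV/TV = %.4f\n",
              d[1], d[2], d[3], object@voxelSize, bvtv(object)))
})

setMethod("show", "ARGResult", function(object) {
  cat(sprintf(
    "ARGResult: %d iterations, selected #%d (threshold %.4g), nested = %s\n",
    length(object@thresholds), object@selectedIteration,
    object@thresholds[object@selectedIteration], object@masksNested))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d voxels, %d nodes, %d termini, length %.3f mm\n",
              sum(object@skeletonMask@voxels), object@nNodes,
              object@nTermini, object@totalLengthMm))
})

setMethod("show", "StructureMetrics", function(object) {
  cat("StructureMetrics:\n")
  print(as.data.frame(object))
})

#' @export
as.data.frame.StructureMetrics <- function(x, ...) {
  data.frame(Tb.Nd = x@tbNd, Tb.Tm = x@tbTm, Tb.Sp = x@tbSp, Tb.Sc = x@tbSc,
             Tb.N = x@tbN, Tb.Th = x@tbTh, BVTV = x@bvtv)
}

setMethod("show", "FEModel", function(object) {
  d <- dim(object@occupancy)
  cat(sprintf(
    "FEModel: %d elements on %dx%dx%d grid, E = %.3g GPa, nu = %.2f (removed %.2f%%)\n",
    sum(object@occupancy@voxels), d[1], d[2], d[3], object@tissueE,
    object@tissueNu, 100 * object@removedFraction))
})

setMethod("show", "StiffnessResult", function(object) {
  cat(sprintf(
    "StiffnessResult: E1 = %.4g, E2 = %.4g, E3 = %.4g GPa; Gmin = %.4g GPa\n",
    object@E[1], object@E[2], object@E[3], object@Gmin))
})

#' Apparent stiffness matrix
#' @param x a [StiffnessResult-class].
#' @return the symmetrized 6x6 Voigt stiffness matrix (GPa).
#' @export
setGeneric("stiffnessMatrix", function(x) standardGeneric("stiffnessMatrix"))

#' @rdname stiffnessMatrix
#' @export
setMethod("stiffnessMatrix", "StiffnessResult", function(x) x@C)

#' Young's moduli and minimum shear modulus
#' @param x a [StiffnessResult-class].
#' @return for `youngsModuli`, length-3 numeric (E1 <= E2 <= E3, GPa);
#'   for `shearMin`, the minimum of G12, G13, G23 (GPa).
#' @export
setGeneric("youngsModuli", function(x) standardGeneric("youngsModuli"))

#' @rdname youngsModuli
#' @export
setMethod("youngsModuli", "StiffnessResult", function(x)
  setNames(x@E, c("E1", "E2", "E3")))

#' @rdname youngsModuli
#' @export
setGeneric("shearMin", function(x) standardGeneric("shearMin"))

#' @rdname youngsModuli
#' @export
setMethod("shearMin", "StiffnessResult", function(x) x@Gmin)
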