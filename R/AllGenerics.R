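#' Accessors for volume-like objects
#'
#' \code{gridData} returns the underlying 3D array; \code{voxelSize} the
#' voxel edge lengths in micrometres.
#'
#' @param x A volume-like object.
#' @return \code{gridData}: the 3D array; \code{voxelSize}: numeric triple
#'   in micrometres.
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))

#' @rdname gridData
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

for (cls in c("Volume3D", "TissueMask", "LabelVolume", "CountVolume",
              "DensityMap", "DetectionMask"))
  setMethod("gridData", cls, function(x) x@data)

for (cls in c("Volume3D", "CountVolume", "DensityMap"))
  setMethod("voxelSize", cls, function(x) x@voxelSize)

#' Number of detected cells in a CellSet
#' @param x A \code{CellSet}.
#' @return Integer count of accepted cells.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "CellSet", function(x) length(x@sizes))

#' Cell sizes, centroids and artefact sizes of a CellSet
#'
#' @param x A \code{CellSet}.
#' @return \code{cellSizes}: integer vector of voxels per cell;
#'   \code{cellCentroids}: numeric matrix (nCells x 3) of fractional voxel
#'   coordinates; \code{artefactSizes}: sizes of components discarded for
#'   exceeding the accepted cluster size.
#' @export
setGeneric("cellSizes", function(x) standardGeneric("cellSizes"))

#' @rdname cellSizes
#' @export
setGeneric("cellCentroids", function(x) standardGeneric("cellCentroids"))

#' @rdname cellSizes
#' @export
setGeneric("artefactSizes", function(x) standardGeneric("artefactSizes"))

setMethod("cellSizes", "CellSet", function(x) x@sizes)
setMethod("cellCentroids", "CellSet", function(x) x@centroids)
setMethod("artefactSizes", "CellSet", function(x) x@artefactSizes)

#' t- and p-value grids of a StatMap
#'
#' @param x A \code{StatMap}.
#' @return \code{tValues}/\code{pValues}: numeric 3D arrays (p is \code{NA}
#'   where undefined); \code{definedMask}: logical 3D array of voxels where
#'   the test is defined.
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))

#' @rdname tValues
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname tValues
#' @export
setGeneric("definedMask", function(x) standardGeneric("definedMask"))

setMethod("tValues", "StatMap", function(x) x@t)
setMethod("pValues", "StatMap", function(x) x@p)
setMethod("definedMask", "StatMap", function(x) x@defined)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D: %d x %d x %d voxels, voxel size %s um\n",
              d[1], d[2], d[3], paste(signif(object@voxelSize, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "CellSet", function(object) {
  cat(sprintf("CellSet: %d cells (sizes %s), %d artefacts\n",
              length(object@sizes),
              if (length(object@sizes)) paste(range(object@sizes), collapse = "-") else "-",
              length(object@artefactSizes)))
})

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("DensityMap: %d x %d x %d voxels, kernel %d^3, max %.3g cells/ul\n",
              d[1], d[2], d[3], object@params@kernelExtent, max(object@data)))
})

setMethod("show", "StatMap", function(object) {
  d <- dim(object@t)
  cat(sprintf("StatMap (%s, two-sided): %d x %d x %d voxels, n = %d vs %d, %.1f%% defined\n",
              object@variant, d[1], d[2], d[3], object@nA, object@nB,
              100 * mean(object@defined)))
})

setMethod("show", "DetectionMask", function(object) {
  cat(sprintf("DetectionMask: %d flagged voxels of %s\n",
              sum(object@data), paste(dim(object@data), collapse = " x ")))
})
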