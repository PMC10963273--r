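#' @import methods
NULL

## ---- Parameter classes -------------------------------------------------

#' Detection parameters for the ratio-based Fos voxel detector
#'
#' The detector flags a voxel when its intensity exceeds its 26 face-, edge-
#' and corner-neighbours (the full 3x3x3 cube minus the centre) by at least
#' \code{thresholdFraction} (default 0.20, i.e. a 20\% increase). Connected
#' components of flagged voxels with between \code{minClusterVoxels} and
#' \code{maxClusterVoxels} voxels (defaults 1 and 8) count as one cell;
#' larger components are recorded as artefacts.
#'
#' @slot thresholdFraction Minimum fractional excess over neighbours
#'   (dimensionless, > 0). A voxel at exactly \code{(1 + f)} times a
#'   neighbour counts as exceeding it.
#' @slot comparisonMode \code{"each-neighbor"} (default): the voxel must
#'   exceed every neighbour individually; \code{"mean-of-neighbors"}: it
#'   must exceed the neighbour mean.
#' @slot minClusterVoxels,maxClusterVoxels Accepted component size range.
#' @slot connectivity Component connectivity: 6, 18 or 26 (default).
#' @export
setClass("DetectionParams", representation(
  thresholdFraction = "numeric",
  comparisonMode    = "character",
  minClusterVoxels  = "integer",
  maxClusterVoxels  = "integer",
  connectivity      = "integer"
))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (length(object@thresholdFraction) != 1L || !is.finite(object@thresholdFraction) ||
      object@thresholdFraction <= 0)
    msg <- c(msg, "thresholdFraction must be a single positive number")
  if (!object@comparisonMode %in% c("each-neighbor", "mean-of-neighbors"))
    msg <- c(msg, "comparisonMode must be 'each-neighbor' or 'mean-of-neighbors'")
  if (object@minClusterVoxels < 1L || object@maxClusterVoxels < object@minClusterVoxels)
    msg <- c(msg, "need 1 <= minClusterVoxels <= maxClusterVoxels")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  if (length(msg)) msg else TRUE
})

#' @param thresholdFraction,comparisonMode,minClusterVoxels,maxClusterVoxels,connectivity
#'   See slot documentation.
#' @return A \code{DetectionParams} object.
#' @rdname DetectionParams-class
#' @export
DetectionParams <- function(thresholdFraction = 0.20,
                            comparisonMode = c("each-neighbor", "mean-of-neighbors"),
                            minClusterVoxels = 1L, maxClusterVoxels = 8L,
                            connectivity = 26L) {
  new("DetectionParams",
      thresholdFraction = thresholdFraction,
      comparisonMode = match.arg(comparisonMode),
      minClusterVoxels = as.integer(minClusterVoxels),
      maxClusterVoxels = as.integer(maxClusterVoxels),
      connectivity = as.integer(connectivity))
}

#' Local-density parameters
#'
#' Local density is the number of detected cells in a sliding uniform cubic
#' window of \code{kernelExtent} voxels per axis, divided by the window's
#' physical volume in microlitres. At the canonical 25 um isotropic grid the
#' default 20x20x20 window has volume 0.125 ul, so one cell in a window
#' contributes 8 cells/ul.
#'
#' @slot kernelExtent Window extent in voxels per axis (>= 1). For even
#'   extents the window spans offsets \code{[-k/2, k/2 - 1]} per axis.
#' @export
setClass("DensityParams", representation(kernelExtent = "integer"))

setValidity("DensityParams", function(object) {
  if (length(object@kernelExtent) != 1L || object@kernelExtent < 1L)
    "kernelExtent must be a single integer >= 1" else TRUE
})

#' @param kernelExtent Window extent in voxels per axis.
#' @return A \code{DensityParams} object.
#' @rdname DensityParams-class
#' @export
DensityParams <- function(kernelExtent = 20L)
  new("DensityParams", kernelExtent = as.integer(kernelExtent))

#' Single-nucleus QC filter parameters
#'
#' Cells with fewer than \code{minUmis} UMIs, fewer than \code{minGenes}
#' detected genes, or a mitochondrial read fraction above
#' \code{maxMitoFraction} are removed; all three bounds are themselves
#' retained (a cell at exactly 800 UMIs, 500 genes and 10\% mito passes).
#'
#' @slot minUmis Minimum UMI count retained (default 800).
#' @slot minGenes Minimum detected-gene count retained (default 500).
#' @slot maxMitoFraction Maximum mitochondrial fraction retained (default 0.10).
#' @export
setClass("QCParams", representation(
  minUmis = "integer", minGenes = "integer", maxMitoFraction = "numeric"))

setValidity("QCParams", function(object) {
  msg <- character()
  if (object@minUmis < 0L) msg <- c(msg, "minUmis must be >= 0")
  if (object@minGenes < 0L) msg <- c(msg, "minGenes must be >= 0")
  if (object@maxMitoFraction < 0 || object@maxMitoFraction > 1)
    msg <- c(msg, "maxMitoFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param minUmis,minGenes,maxMitoFraction See slot documentation.
#' @return A \code{QCParams} object.
#' @rdname QCParams-class
#' @export
QCParams <- function(minUmis = 800L, minGenes = 500L, maxMitoFraction = 0.10)
  new("QCParams", minUmis = as.integer(minUmis), minGenes = as.integer(minGenes),
      maxMitoFraction = maxMitoFraction)

#' IEG activation score parameters
#'
#' @slot iegPanel Character vector of panel gene symbols (default: the
#'   10-gene immediate-early-gene panel, see \code{\link{iegPanelDefault}}).
#' @slot minFrac Minimum fraction of the cluster's cells expressing a panel
#'   gene for it to enter the score (inclusive; default 0.05).
#' @slot alpha Raw-p significance cutoff for a panel gene to enter the score
#'   (strict; default 0.05).
#' @slot scoreMode \code{"neglog_combined_p"} (default): score magnitude is
#'   \code{-log10} of the Fisher-combined p-value; \code{"neglog_chi2_statistic"}:
#'   \code{-log10} of the chi-squared combination statistic itself.
#' @export
setClass("ScoreParams", representation(
  iegPanel = "character", minFrac = "numeric", alpha = "numeric",
  scoreMode = "character"))

setValidity("ScoreParams", function(object) {
  msg <- character()
  if (length(object@iegPanel) < 1L) msg <- c(msg, "iegPanel must be non-empty")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0, 1)")
  if (object@minFrac < 0 || object@minFrac > 1) msg <- c(msg, "minFrac must be in [0, 1]")
  if (!object@scoreMode %in% c("neglog_combined_p", "neglog_chi2_statistic"))
    msg <- c(msg, "unknown scoreMode")
  if (length(msg)) msg else TRUE
})

#' The default 10-gene immediate-early-gene panel
#'
#' Panel of immediate early genes used to score neuronal activation:
#' Fos, Fosl2, Homer1, Nr4a3, Nr4a1, Gem, Jun, Junb, Btg1 and
#' 1700016P03Rik.
#'
#' @return Character vector of 10 gene symbols.
#' @export
iegPanelDefault <- function()
  c("Fos", "Fosl2", "Homer1", "Nr4a3", "Nr4a1",
    "Gem", "Jun", "Junb", "Btg1", "1700016P03Rik")

#' @param iegPanel,minFrac,alpha,scoreMode See slot documentation.
#' @return A \code{ScoreParams} object.
#' @rdname ScoreParams-class
#' @export
ScoreParams <- function(iegPanel = iegPanelDefault(), minFrac = 0.05,
                        alpha = 0.05,
                        scoreMode = c("neglog_combined_p", "neglog_chi2_statistic"))
  new("ScoreParams", iegPanel = iegPanel, minFrac = minFrac, alpha = alpha,
      scoreMode = match.arg(scoreMode))

## ---- Volume classes ----------------------------------------------------

#' A registered 3D intensity volume
#'
#' Scalar fluorescence intensities on a regular grid with physical voxel
#' size. Arrays are indexed \code{[x, y, z]}: the first index is the fastest
#' varying and maps to the first spatial axis of the source file (NIfTI
#' i-axis; TIFF column), the third index is the page/slice axis.
#'
#' @slot data Numeric 3D array (every dimension >= 3, finite values).
#' @slot voxelSize Numeric triple of positive voxel edge lengths in
#'   micrometres, one per array axis.
#' @export
setClass("Volume3D", representation(data = "array", voxelSize = "numeric"))

.validVolumeLike <- function(object, minDim = 1L) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (any(dim(object@data) < minDim))
    msg <- c(msg, sprintf("every dimension must be >= %d", minDim))
  msg
}

setValidity("Volume3D", function(object) {
  msg <- .validVolumeLike(object, minDim = 3L)
  if (!all(is.finite(object@data))) msg <- c(msg, "intensities must be finite")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (um)")
  if (length(msg)) msg else TRUE
})

#' @param data 3D numeric array.
#' @param voxelSize Voxel edge lengths in micrometres.
#' @return A \code{Volume3D}.
#' @rdname Volume3D-class
#' @export
Volume3D <- function(data, voxelSize = c(25, 25, 25)) {
  storage.mode(data) <- "double"
  new("Volume3D", data = data, voxelSize = as.numeric(voxelSize))
}

#' Tissue mask companion to a volume
#'
#' @slot data Logical 3D array, TRUE inside tissue.
#' @export
setClass("TissueMask", representation(data = "array"))

setValidity("TissueMask", function(object) {
  msg <- .validVolumeLike(object)
  if (!is.logical(object@data)) msg <- c(msg, "mask must be logical")
  if (length(msg)) msg else TRUE
})

#' @param data Logical 3D array.
#' @return A \code{TissueMask}.
#' @rdname TissueMask-class
#' @export
TissueMask <- function(data) new("TissueMask", data = data)

#' Integer region-label volume
#'
#' Label 0 is reserved for outside/unlabelled voxels; every nonzero label
#' present in the grid must appear in the label table.
#'
#' @slot data Integer 3D array of non-negative labels.
#' @slot labelTable data.frame with columns \code{label} and \code{name}.
#' @export
setClass("LabelVolume", representation(data = "array", labelTable = "data.frame"))

setValidity("LabelVolume", function(object) {
  msg <- .validVolumeLike(object)
  if (any(object@data < 0)) msg <- c(msg, "labels must be non-negative")
  present <- setdiff(unique(as.vector(object@data)), 0)
  if (!all(c("label", "name") %in% names(object@labelTable)))
    msg <- c(msg, "labelTable needs columns 'label' and 'name'")
  else if (!all(present %in% object@labelTable$label))
    msg <- c(msg, "every nonzero label in data must appear in labelTable")
  if (length(msg)) msg else TRUE
})

#' @param data Integer 3D array.
#' @param labelTable data.frame mapping label to region name; defaults to
#'   \code{region_<label>} names for the labels present.
#' @return A \code{LabelVolume}.
#' @rdname LabelVolume-class
#' @export
LabelVolume <- function(data, labelTable = NULL) {
  storage.mode(data) <- "integer"
  if (is.null(labelTable)) {
    labs <- sort(setdiff(unique(as.vector(data)), 0L))
    labelTable <- data.frame(label = labs, name = sprintf("region_%d", labs))
  }
  new("LabelVolume", data = data, labelTable = labelTable)
}

#' Per-voxel cell count volume
#'
#' Intermediate between detected cells and the density map: each detected
#' cell contributes one count at its (rounded) centroid voxel.
#'
#' @slot data Integer 3D array of non-negative counts.
#' @slot voxelSize Voxel edge lengths in micrometres.
#' @export
setClass("CountVolume", representation(data = "array", voxelSize = "numeric"))

setValidity("CountVolume", function(object) {
  msg <- .validVolumeLike(object)
  if (any(object@data < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (um)")
  if (length(msg)) msg else TRUE
})

#' @param data Integer 3D array of counts.
#' @param voxelSize Voxel edge lengths in micrometres.
#' @return A \code{CountVolume}.
#' @rdname CountVolume-class
#' @export
CountVolume <- function(data, voxelSize = c(25, 25, 25)) {
  storage.mode(data) <- "integer"
  new("CountVolume", data = data, voxelSize = as.numeric(voxelSize))
}

## ---- Result classes ----------------------------------------------------

#' Mask of Fos-candidate voxels
#'
#' @slot data Logical 3D array; flagged voxels never lie on the array edge
#'   nor adjacent to an out-of-tissue voxel.
#' @slot params The \code{DetectionParams} used.
#' @export
setClass("DetectionMask", representation(data = "array", params = "DetectionParams"))

#' Detected Fos-positive cells
#'
#' Connected components of the detection mask within the accepted size
#' range; larger components are retained as artefacts (sizes only).
#'
#' @slot voxels List of integer matrices (one per cell, rows are voxel
#'   coordinates).
#' @slot sizes Integer vector of cell sizes in voxels.
#' @slot centroids Numeric matrix (nCells x 3) of unweighted mean voxel
#'   coordinates.
#' @slot artefactSizes Integer vector of discarded component sizes.
#' @slot shape Dimensions of the source grid.
#' @slot params The \code{DetectionParams} used.
#' @export
setClass("CellSet", representation(
  voxels = "list", sizes = "integer", centroids = "matrix",
  artefactSizes = "integer", shape = "integer", params = "DetectionParams"))

setValidity("CellSet", function(object) {
  msg <- character()
  if (length(object@voxels) != length(object@sizes))
    msg <- c(msg, "voxels and sizes lengths differ")
  if (nrow(object@centroids) != length(object@sizes))
    msg <- c(msg, "centroids row count mismatch")
  if (length(object@sizes) &&
      (any(object@sizes < object@params@minClusterVoxels) ||
       any(object@sizes > object@params@maxClusterVoxels)))
    msg <- c(msg, "cell sizes outside accepted cluster range")
  if (length(msg)) msg else TRUE
})

#' Local cell-density map in cells per microlitre
#'
#' @slot data Numeric non-negative 3D array, cells/ul.
#' @slot params The \code{DensityParams} used.
#' @slot voxelSize Voxel edge lengths in micrometres.
#' @slot totalCells Number of cells in the source count volume (provenance).
#' @export
setClass("DensityMap", representation(
  data = "array", params = "DensityParams", voxelSize = "numeric",
  totalCells = "numeric"))

setValidity("DensityMap", function(object) {
  msg <- .validVolumeLike(object)
  if (any(object@data < 0)) msg <- c(msg, "densities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Voxelwise two-sample t-test map
#'
#' @slot t Numeric 3D array of t statistics.
#' @slot p Numeric 3D array of two-sided p-values; \code{NA} where the test
#'   is undefined (zero variance in both groups with equal means).
#' @slot defined Logical 3D array, TRUE where p is defined.
#' @slot nA,nB Group sizes.
#' @slot variant \code{"student"} or \code{"welch"}.
#' @export
setClass("StatMap", representation(
  t = "array", p = "array", defined = "array",
  nA = "integer", nB = "integer", variant = "character"))

setValidity("StatMap", function(object) {
  msg <- character()
  pv <- object@p[object@defined]
  if (length(pv) && (any(is.na(pv)) || any(pv < 0 | pv > 1)))
    msg <- c(msg, "defined p-values must lie in [0, 1]")
  if (!identical(dim(object@t), dim(object@p)) ||
      !identical(dim(object@t), dim(object@defined)))
    msg <- c(msg, "t, p and defined must share dimensions")
  if (length(msg)) msg else TRUE
})

## ---- Simulation spec classes -------------------------------------------

#' Specification for a synthetic cleared-brain volume
#'
#' Emulates a registered cleared-brain Fos channel: a spatially smooth
#' background field plus white Gaussian noise, with point-like cells planted
#' by a region-wise Poisson process. Each planted cell is a connected voxel
#' cluster whose intensities exceed the local background (the 3x3x3
#' neighbourhood maximum of the noiseless field) by the fractional margin
#' \code{cellMargin} before noise, so a detector with threshold below the
#' margin finds interior single-voxel cells exactly.
#'
#' @slot shape Integer triple of grid dimensions.
#' @slot voxelSize Voxel edge lengths in micrometres.
#' @slot backgroundLevel Mean background intensity (arbitrary units).
#' @slot noiseSd Standard deviation of additive white noise.
#' @slot cellMargin Fractional intensity excess of cell voxels over local
#'   background (e.g. 0.4 = 40\% above). Set below the detector threshold
#'   for negative controls.
#' @slot cellSizeRange Integer pair in [1, 8]: planted cluster sizes are
#'   drawn uniformly from this range.
#' @slot regionDensities Named numeric vector: expected planted cells per
#'   microlitre for each region label (names are label integers).
#' @slot seed Integer seed; identical specs reproduce bit-identical output.
#' @export
setClass("VolumeSimSpec", representation(
  shape = "integer", voxelSize = "numeric", backgroundLevel = "numeric",
  noiseSd = "numeric", cellMargin = "numeric", cellSizeRange = "integer",
  regionDensities = "numeric", seed = "integer"))

setValidity("VolumeSimSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 5L))
    msg <- c(msg, "shape must be three dimensions, each >= 5")
  if (any(object@regionDensities < 0)) msg <- c(msg, "regionDensities must be >= 0")
  if (is.null(names(object@regionDensities)))
    msg <- c(msg, "regionDensities must be named by region label")
  if (length(object@cellSizeRange) != 2L || object@cellSizeRange[1] < 1L ||
      object@cellSizeRange[2] > 8L || diff(object@cellSizeRange) < 0)
    msg <- c(msg, "cellSizeRange must be an ordered pair within [1, 8]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param shape,voxelSize,backgroundLevel,noiseSd,cellMargin,cellSizeRange,regionDensities,seed
#'   See slot documentation.
#' @return A \code{VolumeSimSpec}.
#' @rdname VolumeSimSpec-class
#' @export
VolumeSimSpec <- function(shape = c(48L, 48L, 48L), voxelSize = c(25, 25, 25),
                          backgroundLevel = 100, noiseSd = 2, cellMargin = 0.4,
                          cellSizeRange = c(1L, 1L),
                          regionDensities = c(`1` = 40, `2` = 40, `3` = 40),
                          seed = 1L) {
  new("VolumeSimSpec", shape = as.integer(shape), voxelSize = as.numeric(voxelSize),
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      cellMargin = cellMargin, cellSizeRange = as.integer(cellSizeRange),
      regionDensities = regionDensities, seed = as.integer(seed))
}

#' Specification for a two-group cohort of synthetic volumes
#'
#' @slot base The shared \code{VolumeSimSpec}; per-mouse seeds are derived
#'   from its seed.
#' @slot densitiesA,densitiesB Named numeric vectors of per-region planted
#'   densities (cells/ul) for the two groups.
#' @slot nPerGroup Mice per group (default 4, >= 2).
#' @export
setClass("CohortSimSpec", representation(
  base = "VolumeSimSpec", densitiesA = "numeric", densitiesB = "numeric",
  nPerGroup = "integer"))

setValidity("CohortSimSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2 (t-test undefined otherwise)")
  if (!identical(names(object@densitiesA), names(object@densitiesB)))
    msg <- c(msg, "densitiesA and densitiesB must cover the same regions")
  if (length(msg)) msg else TRUE
})

#' @param base,densitiesA,densitiesB,nPerGroup See slot documentation.
#' @return A \code{CohortSimSpec}.
#' @rdname CohortSimSpec-class
#' @export
CohortSimSpec <- function(base = VolumeSimSpec(),
                          densitiesA = base@regionDensities,
                          densitiesB = base@regionDensities,
                          nPerGroup = 4L)
  new("CohortSimSpec", base = base, densitiesA = densitiesA,
      densitiesB = densitiesB, nPerGroup = as.integer(nPerGroup))

#' Specification for a synthetic single-nucleus RNA-seq experiment
#'
#' Negative-binomial counts with cluster structure, two conditions
#' (\code{control} vs \code{stimulated}) with \code{samplesPerCondition}
#' samples each, and a planted condition effect of \code{+iegLog2fc} log2
#' fold change on the panel genes in activated clusters (\code{-iegLog2fc}
#' in inhibited clusters).
#'
#' @slot nGenes,nClusters,cellsPerCluster Matrix geometry.
#' @slot samplesPerCondition Samples per condition (default 2).
#' @slot iegPanel Panel gene symbols, included in the simulated gene list.
#' @slot activatedClusters,inhibitedClusters Integer cluster ids carrying
#'   the planted effect.
#' @slot iegLog2fc Planted log2 fold change (stimulated vs control).
#' @slot dispersion NB overdispersion (variance = mu + dispersion * mu^2).
#' @slot librarySizeRange Integer pair: per-cell library sizes drawn
#'   uniformly from this range.
#' @slot mitoFractionRange Pair in [0, 1]: per-cell mitochondrial fraction.
#' @slot seed Integer seed.
#' @export
setClass("SnRnaSimSpec", representation(
  nGenes = "integer", nClusters = "integer", cellsPerCluster = "integer",
  samplesPerCondition = "integer", iegPanel = "character",
  activatedClusters = "integer", inhibitedClusters = "integer",
  iegLog2fc = "numeric", dispersion = "numeric",
  librarySizeRange = "integer", mitoFractionRange = "numeric",
  seed = "integer"))

setValidity("SnRnaSimSpec", function(object) {
  msg <- character()
  ids <- seq_len(object@nClusters)
  if (!all(object@activatedClusters %in% ids) ||
      !all(object@inhibitedClusters %in% ids))
    msg <- c(msg, "effect clusters must be existing cluster ids")
  if (length(intersect(object@activatedClusters, object@inhibitedClusters)))
    msg <- c(msg, "a cluster cannot be both activated and inhibited")
  if (object@nGenes < length(object@iegPanel) + 1L)
    msg <- c(msg, "nGenes too small to contain the IEG panel")
  if (object@samplesPerCondition < 2L)
    msg <- c(msg, "samplesPerCondition must be >= 2")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param nGenes,nClusters,cellsPerCluster,samplesPerCondition,iegPanel,activatedClusters,inhibitedClusters,iegLog2fc,dispersion,librarySizeRange,mitoFractionRange,seed
#'   See slot documentation.
#' @return A \code{SnRnaSimSpec}.
#' @rdname SnRnaSimSpec-class
#' @export
SnRnaSimSpec <- function(nGenes = 1000L, nClusters = 6L, cellsPerCluster = 400L,
                         samplesPerCondition = 2L, iegPanel = iegPanelDefault(),
                         activatedClusters = 1L, inhibitedClusters = 2L,
                         iegLog2fc = 1.5, dispersion = 0.15,
                         librarySizeRange = c(2000L, 8000L),
                         mitoFractionRange = c(0, 0.08), seed = 1L)
  new("SnRnaSimSpec", nGenes = as.integer(nGenes), nClusters = as.integer(nClusters),
      cellsPerCluster = as.integer(cellsPerCluster),
      samplesPerCondition = as.integer(samplesPerCondition),
      iegPanel = iegPanel, activatedClusters = as.integer(activatedClusters),
      inhibitedClusters = as.integer(inhibitedClusters), iegLog2fc = iegLog2fc,
      dispersion = dispersion, librarySizeRange = as.integer(librarySizeRange),
      mitoFractionRange = as.numeric(mitoFractionRange), seed = as.integer(seed))
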