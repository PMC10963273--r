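#' Flag Fos-candidate voxels by the ratio rule
#'
#' A voxel is flagged when (a) its full 26-voxel neighbourhood (the 3x3x3
#' cube minus the centre) exists — i.e. the voxel is not on the array edge —
#' and the voxel and all 26 neighbours lie inside the tissue mask, and (b)
#' its intensity is at least \code{(1 + thresholdFraction)} times every
#' neighbour's intensity (default mode), or times the neighbour mean under
#' \code{comparisonMode = "mean-of-neighbors"}. The rule is a ratio, so the
#' result is invariant to rescaling all intensities by a positive constant
#' (but not to additive offsets).
#'
#' @param volume A \code{\link{Volume3D}}.
#' @param mask Optional \code{\link{TissueMask}} of the same shape; when
#'   omitted the whole grid counts as tissue and only the array edge is
#'   excluded.
#' @param params A \code{\link{DetectionParams}}.
#' @return A \code{DetectionMask}.
#' @export
detectFosVoxels <- function(volume, mask = NULL, params = DetectionParams()) {
  v <- gridData(volume)
  d <- dim(v)
  if (any(d < 3L))
    stopDomain("detection needs every dimension >= 3, got ", paste(d, collapse = "x"))
  if (is.null(mask)) {
    m <- NULL
  } else {
    m <- gridData(mask)
    checkSameShape(v, m, "volume and tissue mask")
  }
  thr <- 1 + params@thresholdFraction
  i1 <- 2:(d[1] - 1L); i2 <- 2:(d[2] - 1L); i3 <- 2:(d[3] - 1L)
  core <- v[i1, i2, i3, drop = FALSE]
  inTissue <- if (is.null(m)) TRUE else m[i1, i2, i3, drop = FALSE]
  eachMode <- params@comparisonMode == "each-neighbor"
  pass <- if (eachMode) array(TRUE, dim(core)) else array(0, dim(core))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    nb <- v[i1 + dx, i2 + dy, i3 + dz, drop = FALSE]
    if (!is.null(m))
      inTissue <- inTissue & m[i1 + dx, i2 + dy, i3 + dz, drop = FALSE]
    if (eachMode) pass <- pass & (core >= thr * nb)
    else pass <- pass + nb
  }
  if (!eachMode) pass <- core >= thr * (pass / 26)
  flagged <- array(FALSE, d)
  flagged[i1, i2, i3] <- pass & inTissue
  new("DetectionMask", data = flagged, params = params)
}

#' Group flagged voxels into cells and artefacts
#'
#' Connected components of the detection mask are computed under
#' \code{params@connectivity} (26 by default). Components whose voxel count
#' lies within \code{[minClusterVoxels, maxClusterVoxels]} (defaults 1-8)
#' each count as one Fos-positive cell; larger (or smaller, if the minimum
#' is raised) components are recorded as artefacts. Cell centroids are
#' unweighted means of member voxel coordinates.
#'
#' @param mask A \code{DetectionMask} (or any logical-grid object produced
#'   with compatible parameters).
#' @param params A \code{\link{DetectionParams}}; defaults to the mask's own.
#' @return A \code{\link{CellSet}}.
#' @export
findCells <- function(mask, params = NULL) {
  if (is.null(params)) params <- mask@params
  flagged <- gridData(mask)
  d <- dim(flagged)
  coords <- which(flagged, arr.ind = TRUE)
  dimnames(coords) <- NULL
  n <- nrow(coords)
  emptySet <- function() new("CellSet", voxels = list(), sizes = integer(),
                             centroids = matrix(numeric(), 0L, 3L),
                             artefactSizes = integer(), shape = as.integer(d),
                             params = params)
  if (n == 0L) return(emptySet())

  lin <- (coords[, 1] - 1) + (coords[, 2] - 1) * d[1] + (coords[, 3] - 1) * d[1] * d[2]
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- connectivityOffsets(params@connectivity)
  # each unordered neighbour pair is seen once from its lexicographically
  # smaller offset, so half the offset set suffices
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
                (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nx <- coords[, 1] + o[1]; ny <- coords[, 2] + o[2]; nz <- coords[, 3] + o[3]
    valid <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(valid)) next
    nlin <- (nx[valid] - 1) + (ny[valid] - 1) * d[1] + (nz[valid] - 1) * d[1] * d[2]
    j <- match(nlin, lin)
    hit <- which(!is.na(j))
    ii <- which(valid)[hit]; jj <- j[hit]
    for (t in seq_along(ii)) {
      ri <- findRoot(ii[t]); rj <- findRoot(jj[t])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  comp <- match(root, unique(root))
  sizes <- tabulate(comp)
  keep <- sizes >= params@minClusterVoxels & sizes <= params@maxClusterVoxels

  cellIds <- which(keep)
  voxels <- lapply(cellIds, function(cid) coords[comp == cid, , drop = FALSE])
  centroids <- if (length(cellIds))
    t(vapply(voxels, colMeans, numeric(3))) else matrix(numeric(), 0L, 3L)
  new("CellSet", voxels = voxels, sizes = as.integer(sizes[keep]),
      centroids = centroids, artefactSizes = as.integer(sizes[!keep]),
      shape = as.integer(d), params = params)
}

#' Rasterise detected cells into a per-voxel count volume
#'
#' Each cell contributes exactly one count at its centroid voxel; fractional
#' centroid components are rounded to the nearest index with half-way ties
#' going to the lower index. The total count equals the number of cells.
#'
#' @param cells A \code{\link{CellSet}}.
#' @param shape Grid dimensions (defaults to the source grid's).
#' @param voxelSize Voxel edge lengths in micrometres.
#' @return A \code{\link{CountVolume}}.
#' @export
cellsToCounts <- function(cells, shape = cells@shape, voxelSize = c(25, 25, 25)) {
  shape <- as.integer(shape)
  counts <- array(0L, shape)
  if (nCells(cells) > 0L) {
    # round half toward the lower index: 2.5 -> 2, 2.51 -> 3
    idx <- ceiling(cellCentroids(cells) - 0.5)
    if (any(idx < 1L) || any(idx > matrix(shape, nrow(idx), 3L, byrow = TRUE)))
      stopDomain("cell centroid outside the target grid")
    lin <- (idx[, 1] - 1L) + (idx[, 2] - 1L) * shape[1] +
      (idx[, 3] - 1L) * shape[1] * shape[2] + 1L
    tab <- table(lin)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  CountVolume(counts, voxelSize = voxelSize)
}
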