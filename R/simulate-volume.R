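#' Slab-partition label volume
#'
#' Deterministic region geometry used by the volume simulator: the grid is
#' split into contiguous slabs of (near-)equal thickness along the third
#' axis, one slab per requested label.
#'
#' @param shape Integer triple of grid dimensions.
#' @param labels Integer vector of region labels, one slab each (in
#'   ascending label order along the axis).
#' @return A \code{\link{LabelVolume}}.
#' @export
slabLabelVolume <- function(shape, labels) {
  shape <- as.integer(shape)
  labels <- sort(as.integer(labels))
  nz <- shape[3]
  bounds <- round(seq(0, nz, length.out = length(labels) + 1))
  sliceLab <- rep(labels, times = diff(bounds))
  arr <- array(rep(sliceLab, each = shape[1] * shape[2]), shape)
  LabelVolume(arr)
}

# 3x3x3 neighbourhood maximum of the background field at given voxels
.localMax3 <- function(field, vox) {
  d <- dim(field)
  vapply(seq_len(nrow(vox)), function(i) {
    x <- vox[i, 1]; y <- vox[i, 2]; z <- vox[i, 3]
    max(field[max(1, x - 1):min(d[1], x + 1),
              max(1, y - 1):min(d[2], y + 1),
              max(1, z - 1):min(d[3], z + 1)])
  }, numeric(1))
}

#' Simulate a ground-truthed cleared-brain volume
#'
#' Builds a smooth background field (a gently modulated sinusoidal surface
#' around \code{backgroundLevel}) on the slab-region geometry of
#' \code{\link{slabLabelVolume}}, plants cells by a per-region Poisson
#' process at the requested densities (cells per microlitre of region
#' volume), and adds white Gaussian noise. Every planted cell is a
#' 26-connected voxel cluster of a size drawn from \code{cellSizeRange};
#' each of its voxels is set, before noise, to \code{(1 + cellMargin)}
#' times the local (3x3x3 maximum) background, so a ratio detector with
#' threshold below \code{cellMargin} flags interior single-voxel cells
#' exactly. Cell seeds are placed at least one voxel away from the array
#' edge; overlaps between cells are allowed (merged clusters are a
#' documented false-negative mode of the downstream 1-8-voxel cell rule).
#'
#' @param spec A \code{\link{VolumeSimSpec}}.
#' @return List with elements \code{volume} (\code{Volume3D}), \code{mask}
#'   (all-tissue \code{TissueMask}), \code{labels} (\code{LabelVolume}),
#'   \code{cells} (ground-truth \code{CellSet}) and \code{regionCounts}
#'   (data.frame of planted cells per region).
#' @export
simulateVolume <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, .simulateVolumeImpl(spec))
}

.simulateVolumeImpl <- function(spec) {
  d <- spec@shape
  labs <- suppressWarnings(as.integer(names(spec@regionDensities)))
  if (any(is.na(labs)))
    stopDomain("regionDensities names must be integer region labels")
  labels <- slabLabelVolume(d, labs)
  labArr <- gridData(labels)

  # smooth low-frequency background: one sinusoidal mode with random phases
  ph <- stats::runif(3, 0, 2 * pi)
  gx <- sin(2 * pi * seq_len(d[1]) / d[1] + ph[1])
  gy <- sin(2 * pi * seq_len(d[2]) / d[2] + ph[2])
  gz <- sin(2 * pi * seq_len(d[3]) / d[3] + ph[3])
  field <- spec@backgroundLevel *
    (1 + 0.05 * outer(outer(gx, gy), gz))
  dim(field) <- d

  voxUl <- voxelVolumeUl(spec@voxelSize)
  interior <- array(FALSE, d)
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE

  allVox <- list(); allSizes <- integer(); regionCounts <- integer(length(labs))
  for (ri in seq_along(labs)) {
    inRegion <- labArr == labs[ri]
    lambda <- spec@regionDensities[ri] * sum(inRegion) * voxUl
    nCellsR <- stats::rpois(1, lambda)
    regionCounts[ri] <- nCellsR
    if (nCellsR == 0L) next
    cand <- which(inRegion & interior, arr.ind = TRUE)
    dimnames(cand) <- NULL
    seeds <- cand[sample.int(nrow(cand), nCellsR, replace = TRUE), , drop = FALSE]
    for (ci in seq_len(nCellsR)) {
      size <- if (spec@cellSizeRange[1] == spec@cellSizeRange[2])
        spec@cellSizeRange[1]
      else sample(spec@cellSizeRange[1]:spec@cellSizeRange[2], 1L)
      vox <- matrix(seeds[ci, ], 1L, 3L)
      while (nrow(vox) < size) {
        from <- vox[sample.int(nrow(vox), 1L), ]
        off <- connectivityOffsets(26L)[sample.int(26L, 1L), ]
        cand2 <- from + off
        if (any(cand2 < 1L) || any(cand2 > d)) next
        if (any(vox[, 1] == cand2[1] & vox[, 2] == cand2[2] & vox[, 3] == cand2[3])) next
        vox <- rbind(vox, cand2)
      }
      allVox[[length(allVox) + 1L]] <- vox
      allSizes <- c(allSizes, nrow(vox))
    }
  }

  signal <- field
  for (vox in allVox) {
    vals <- (1 + spec@cellMargin) * .localMax3(field, vox)
    lin <- (vox[, 1] - 1L) + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2] + 1L
    signal[lin] <- pmax(signal[lin], vals)
  }
  noisy <- signal + if (spec@noiseSd > 0) stats::rnorm(prod(d), 0, spec@noiseSd) else 0
  dim(noisy) <- d

  centroids <- if (length(allVox))
    t(vapply(allVox, colMeans, numeric(3))) else matrix(numeric(), 0L, 3L)
  truth <- new("CellSet", voxels = allVox, sizes = allSizes,
               centroids = centroids, artefactSizes = integer(),
               shape = d, params = DetectionParams())
  list(volume = Volume3D(noisy, voxelSize = spec@voxelSize),
       mask = TissueMask(array(TRUE, d)),
       labels = labels,
       cells = truth,
       regionCounts = data.frame(label = labs, nCells = regionCounts))
}

#' Simulate a two-group cohort of volumes
#'
#' Generates \code{nPerGroup} volumes per group that differ only in the
#' per-region planted densities (\code{densitiesA} vs \code{densitiesB});
#' region geometry and the tissue mask are shared. Per-mouse seeds are
#' derived deterministically from the base seed as
#' \code{seed + 1000 * (group - 1) + mouse}, so a cohort is reproduced
#' bit-identically from its spec.
#'
#' @param spec A \code{\link{CohortSimSpec}}.
#' @return List with \code{groupA} and \code{groupB} (lists of per-mouse
#'   \code{simulateVolume} results), the shared \code{labels} and the
#'   \code{spec}.
#' @export
simulateCohort <- function(spec) {
  validObject(spec)
  gen <- function(group, densities) {
    lapply(seq_len(spec@nPerGroup), function(i) {
      s <- spec@base
      s@regionDensities <- densities
      s@seed <- spec@base@seed + 1000L * (group - 1L) + i
      simulateVolume(s)
    })
  }
  a <- gen(1L, spec@densitiesA)
  b <- gen(2L, spec@densitiesB)
  list(groupA = a, groupB = b, labels = a[[1]]$labels, spec = spec)
}
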