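# Separable sliding box sum. Window offsets per axis are [-floor(k/2),
# k - floor(k/2) - 1]: symmetric for odd k; for even k (the default 20) the
# window spans [-k/2, k/2 - 1]. Edges are zero-padded.
boxSum3D <- function(arr, k) {
  lo <- -(k %/% 2L)
  hi <- k - (k %/% 2L) - 1L
  axisSum <- function(a) {
    # box-sum along the first axis of a 3D array via cumulative sums
    d <- dim(a)
    m <- matrix(a, d[1], d[2] * d[3])
    cs <- rbind(0, apply(m, 2, cumsum))
    i <- seq_len(d[1])
    out <- cs[pmin(d[1], i + hi) + 1L, , drop = FALSE] -
           cs[pmax(0L, i + lo - 1L) + 1L, , drop = FALSE]
    array(out, d)
  }
  out <- axisSum(arr)
  out <- aperm(axisSum(aperm(out, c(2, 3, 1))), c(3, 1, 2))
  aperm(axisSum(aperm(out, c(3, 1, 2))), c(2, 3, 1))
}

#' Local Fos-cell density in cells per microlitre
#'
#' Counts cells in a sliding uniform cubic window of
#' \code{params@kernelExtent} voxels per axis (a plain box convolution of
#' the count volume) and divides by the window's full physical volume in
#' microlitres. Windows are zero-padded at the array edge but still
#' normalised by the full window volume, so densities within one window
#' width of the edge are biased low; interior totals are conserved exactly.
#'
#' @param counts A \code{\link{CountVolume}}.
#' @param params A \code{\link{DensityParams}} (default: 20-voxel window).
#' @return A \code{\link{DensityMap}} in cells/ul.
#' @examples
#' cv <- CountVolume(array(0L, c(44, 44, 44)))
#' cv@data[22, 22, 22] <- 1L
#' dm <- localDensity(cv)      # plateau of 8 cells/ul around the cell
#' max(gridData(dm))
#' @export
localDensity <- function(counts, params = DensityParams()) {
  arr <- gridData(counts)
  k <- params@kernelExtent
  if (any(dim(arr) < k))
    stopDomain("kernel extent ", k, " exceeds a volume dimension (",
               paste(dim(arr), collapse = "x"), ")")
  windowUl <- as.numeric(k)^3 * voxelVolumeUl(voxelSize(counts))
  dens <- boxSum3D(arr + 0, k) / windowUl
  # box sums of integer counts: clip away negative floating-point dust
  dens[dens < 0] <- 0
  new("DensityMap", data = dens, params = params,
      voxelSize = voxelSize(counts), totalCells = sum(arr))
}

#' Voxelwise two-sample t-test between groups of density maps
#'
#' Computes a per-voxel two-sided two-sample t statistic and p-value between
#' two groups of aligned density maps. The default Student variant pools the
#' within-group variances (df = nA + nB - 2); Welch's unequal-variance
#' form is available. Voxels where both groups have zero variance are
#' undefined when the group means are also equal (t = 0, p = NA, excluded
#' from \code{definedMask}); with unequal means the statistic is infinite
#' and p = 0.
#'
#' @param groupA,groupB Lists of \code{\link{DensityMap}} objects (>= 2
#'   each) with identical shapes and kernel parameters.
#' @param variant \code{"student"} (default) or \code{"welch"}.
#' @return A \code{\link{StatMap}}.
#' @export
voxelwiseTTest <- function(groupA, groupB, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L) stopDomain("each group needs at least 2 density maps")
  maps <- c(groupA, groupB)
  d <- dim(gridData(maps[[1]]))
  k <- maps[[1]]@params@kernelExtent
  for (m in maps[-1]) {
    checkSameShape(gridData(maps[[1]]), gridData(m), "density maps")
    if (m@params@kernelExtent != k)
      stopDomain("density maps were built with different kernel extents")
  }
  nv <- prod(d)
  A <- vapply(groupA, function(m) as.vector(gridData(m)), numeric(nv))
  B <- vapply(groupB, function(m) as.vector(gridData(m)), numeric(nv))
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  diffAB <- mA - mB
  if (variant == "student") {
    df <- rep.int(nA + nB - 2, nv)
    se <- sqrt(((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2) * (1 / nA + 1 / nB))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- se^4 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  tstat <- diffAB / se
  p <- rep.int(NA_real_, nv)
  ok <- se > 0
  p[ok] <- 2 * stats::pt(-abs(tstat[ok]), df[ok])
  degenerate <- !ok                        # zero variance in both groups
  tstat[degenerate & diffAB == 0] <- 0
  tstat[degenerate & diffAB != 0] <- sign(diffAB[degenerate & diffAB != 0]) * Inf
  p[degenerate & diffAB != 0] <- 0
  defined <- ok | (degenerate & diffAB != 0)
  new("StatMap", t = array(tstat, d), p = array(p, d),
      defined = array(defined, d), nA = as.integer(nA), nB = as.integer(nB),
      variant = variant)
}

#' Region-level summary of a density or statistic map
#'
#' Aggregates a \code{\link{DensityMap}} or \code{\link{StatMap}} over the
#' nonzero regions of a label volume. For density maps the summary is the
#' per-region mean density; for statistic maps the mean and minimum defined
#' p-value and the fraction of defined voxels with p below \code{alpha}.
#'
#' @param map A \code{DensityMap} or \code{StatMap}.
#' @param labels A \code{\link{LabelVolume}} of the same shape.
#' @param alpha Significance level for the significant-fraction column.
#' @return data.frame with one row per nonzero label.
#' @export
summarizeRegions <- function(map, labels, alpha = 0.05) {
  lab <- gridData(labels)
  ref <- if (is(map, "StatMap")) map@p else gridData(map)
  checkSameShape(ref, lab, "map and label volume")
  labs <- sort(setdiff(unique(as.vector(lab)), 0L))
  tab <- labels@labelTable
  out <- data.frame(label = labs,
                    name = tab$name[match(labs, tab$label)],
                    nVoxels = integer(length(labs)))
  if (is(map, "StatMap")) {
    out$meanP <- out$minP <- out$fracSignificant <- rep(NA_real_, length(labs))
    for (i in seq_along(labs)) {
      inR <- lab == labs[i]
      out$nVoxels[i] <- sum(inR)
      pv <- map@p[inR & map@defined]
      if (length(pv)) {
        out$meanP[i] <- mean(pv)
        out$minP[i] <- min(pv)
        out$fracSignificant[i] <- mean(pv < alpha)
      }
    }
    out <- out[c("label", "name", "nVoxels", "meanP", "minP", "fracSignificant")]
  } else {
    vals <- gridData(map)
    out$meanDensity <- rep(NA_real_, length(labs))
    for (i in seq_along(labs)) {
      inR <- lab == labs[i]
      out$nVoxels[i] <- sum(inR)
      out$meanDensity[i] <- mean(vals[inR])
    }
  }
  out
}
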