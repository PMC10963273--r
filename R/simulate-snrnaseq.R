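#' Simulate a single-nucleus RNA-seq experiment with planted IEG effects
#'
#' Draws negative-binomial counts for \code{nGenes} genes (the IEG panel
#' plus numbered filler genes) across \code{nClusters} clusters of
#' \code{cellsPerCluster} cells, split evenly between a \code{control} and a
#' \code{stimulated} condition with \code{samplesPerCondition} samples each.
#' Gene relative-abundance profiles carry mild cluster structure (a random
#' 5\% of genes per cluster are 4-fold enriched) and small lognormal
#' sample-level effects; panel genes get an elevated baseline so they are
#' detected in well over 5\% of cells. In activated clusters panel genes
#' have an expected log2 fold change of \code{+iegLog2fc} in stimulated vs
#' control cells (\code{-iegLog2fc} in inhibited clusters); all other
#' cluster/gene combinations are null.
#'
#' @param spec A \code{\link{SnRnaSimSpec}}.
#' @return A \code{SingleCellExperiment} with a sparse \code{counts} assay;
#'   \code{colData} columns \code{cell}, \code{sample}, \code{condition},
#'   \code{cluster}, \code{umi_count}, \code{gene_count},
#'   \code{mito_fraction}; and \code{metadata(sce)$truth}, a data.frame of
#'   the planted per-(cluster, gene) log2 fold changes.
#' @export
simulateSnRnaSeq <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, .simulateSnRnaSeqImpl(spec))
}

.simulateSnRnaSeqImpl <- function(spec) {
  nPanel <- length(spec@iegPanel)
  genes <- c(spec@iegPanel,
             sprintf("gene%04d", seq_len(spec@nGenes - nPanel)))
  nG <- spec@nGenes

  # baseline relative abundances; panel genes pinned to a moderate level so
  # the 5%-of-cells expression filter is comfortably met
  w <- stats::rlnorm(nG, meanlog = 0, sdlog = 1.2)
  w[seq_len(nPanel)] <- stats::median(w) * 8

  # cluster structure: each cluster 4-fold enriches a random 5% of the
  # filler genes (never the panel, which must stay interpretable)
  clusterMult <- matrix(1, nG, spec@nClusters)
  nMark <- max(1L, round(0.05 * (nG - nPanel)))
  for (k in seq_len(spec@nClusters)) {
    idx <- nPanel + sample.int(nG - nPanel, nMark)
    clusterMult[idx, k] <- 4
  }

  conditions <- c("control", "stimulated")
  sampleNames <- as.vector(outer(seq_len(spec@samplesPerCondition), conditions,
                                 function(i, cond) paste0(cond, "_", i)))
  sampleCondition <- rep(conditions, each = spec@samplesPerCondition)
  sampleEffect <- stats::rlnorm(length(sampleNames), 0, 0.1)

  nCells <- spec@nClusters * spec@cellsPerCluster
  cluster <- rep(seq_len(spec@nClusters), each = spec@cellsPerCluster)
  sampleIdx <- unlist(lapply(seq_len(spec@nClusters), function(k)
    sample(rep_len(seq_along(sampleNames), spec@cellsPerCluster))))
  condition <- sampleCondition[sampleIdx]
  libSize <- sample(spec@librarySizeRange[1]:spec@librarySizeRange[2],
                    nCells, replace = TRUE)

  fcUp <- 2^spec@iegLog2fc
  counts <- matrix(0L, nG, nCells)
  for (k in seq_len(spec@nClusters)) {
    prof <- w * clusterMult[, k]
    for (cond in conditions) {
      cellsKC <- which(cluster == k & condition == cond)
      if (!length(cellsKC)) next
      p <- prof
      if (cond == "stimulated") {
        if (k %in% spec@activatedClusters) p[seq_len(nPanel)] <- p[seq_len(nPanel)] * fcUp
        if (k %in% spec@inhibitedClusters) p[seq_len(nPanel)] <- p[seq_len(nPanel)] / fcUp
      }
      scale <- libSize[cellsKC] * sampleEffect[sampleIdx[cellsKC]]
      mu <- (p / sum(p)) %o% scale
      counts[, cellsKC] <- stats::rnbinom(length(mu), size = 1 / spec@dispersion,
                                          mu = mu)
    }
  }
  dimnames(counts) <- list(genes, sprintf("cell%05d", seq_len(nCells)))

  truthLfc <- rep(0, spec@nClusters)
  truthLfc[spec@activatedClusters] <- spec@iegLog2fc
  truthLfc[spec@inhibitedClusters] <- -spec@iegLog2fc
  truth <- data.frame(
    cluster = rep(seq_len(spec@nClusters), each = nPanel),
    gene = rep(spec@iegPanel, spec@nClusters),
    log2fc = rep(truthLfc, each = nPanel))

  cd <- S4Vectors::DataFrame(
    cell = colnames(counts),
    sample = sampleNames[sampleIdx],
    condition = condition,
    cluster = cluster,
    umi_count = colSums(counts),
    gene_count = colSums(counts > 0L),
    mito_fraction = stats::runif(nCells, spec@mitoFractionRange[1],
                                 spec@mitoFractionRange[2]))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = cd)
  S4Vectors::metadata(sce)$truth <- truth
  S4Vectors::metadata(sce)$spec <- spec
  sce
}

#' Write a simulated experiment as MatrixMarket + TSV sidecars
#'
#' Writes \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv}, a cell
#' metadata TSV and the ground-truth effect TSV into a directory.
#'
#' @param sce A \code{SingleCellExperiment} from \code{\link{simulateSnRnaSeq}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSnRnaSeq <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  utils::write.table(as.data.frame(SummarizedExperiment::colData(sce)),
                     file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- S4Vectors::metadata(sce)$truth
  if (!is.null(truth))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
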