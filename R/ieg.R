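#' Quality-control filter for single-nucleus cells
#'
#' Removes cells with fewer than \code{minUmis} UMIs, fewer than
#' \code{minGenes} detected genes, or a mitochondrial fraction above
#' \code{maxMitoFraction}. All bounds are retaining: a cell at exactly 800
#' UMIs, 500 genes and a 10\% mitochondrial rate passes the defaults.
#'
#' @param cellMetrics data.frame (or DataFrame) with columns \code{cell},
#'   \code{umi_count}, \code{gene_count}, \code{mito_fraction}.
#' @param params A \code{\link{QCParams}}.
#' @return Character vector of retained cell ids.
#' @export
qcFilterCells <- function(cellMetrics, params = QCParams()) {
  cm <- as.data.frame(cellMetrics)
  need <- c("cell", "umi_count", "gene_count", "mito_fraction")
  if (!all(need %in% names(cm)))
    stopDomain("cellMetrics needs columns: ", paste(need, collapse = ", "))
  if (nrow(cm) == 0L) return(character())
  with(cm, {
    if (any(!is.finite(umi_count)) || any(!is.finite(gene_count)) ||
        any(!is.finite(mito_fraction)))
      stopDomain("cell metrics must be finite")
    if (any(umi_count < 0) || any(gene_count < 0))
      stopDomain("counts must be non-negative")
    if (any(mito_fraction < 0 | mito_fraction > 1))
      stopDomain("mito_fraction must lie in [0, 1]")
  })
  keep <- cm$umi_count >= params@minUmis &
    cm$gene_count >= params@minGenes &
    cm$mito_fraction <= params@maxMitoFraction
  as.character(cm$cell[keep])
}

#' Holm-Bonferroni step-down adjustment
#'
#' Standard step-down family-wise error rate correction (monotone, capped at
#' 1, input order preserved); delegates to \code{stats::p.adjust} after
#' validating the input range.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, elementwise >= the raw ones.
#' @export
holmBonferroni <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stopDomain("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Combine p-values by Fisher's method
#'
#' The combination statistic is \eqn{-2 \sum_i \ln p_i}, distributed as
#' chi-squared with \eqn{2k} degrees of freedom under the joint null of
#' \eqn{k} independent tests; the combined p-value is its upper-tail
#' probability. For a single input p the combined p equals the input.
#'
#' @param p Non-empty numeric vector of p-values in (0, 1].
#' @return List with \code{statistic}, \code{df} and \code{combined_p}.
#' @examples
#' fisherCombine(c(0.01, 0.04))  # statistic ~ 15.65, df 4
#' @export
fisherCombine <- function(p) {
  if (length(p) == 0L) stopDomain("fisherCombine needs at least one p-value")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stopDomain("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = stat, df = df,
       combined_p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

## ---- Differential expression reference producers -----------------------

.cp10k <- function(counts) {
  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  if (methods::is(counts, "Matrix"))
    counts %*% Matrix::Diagonal(x = 1e4 / lib)
  else
    sweep(counts, 2L, lib / 1e4, "/")
}

#' Per-cluster differential expression between conditions
#'
#' A pluggable reference producer for the per-(cluster, gene) test feeding
#' the IEG activation score. Two methods are available behind the same
#' table interface:
#' \describe{
#'   \item{\code{pseudobulk_t}}{(default) cells are normalised to counts
#'   per 10k, averaged within each (cluster, sample), and the per-sample
#'   means are compared between conditions by a two-sided two-sample
#'   Student t-test. Respects sample-level replication (2 samples per
#'   condition by design).}
#'   \item{\code{percell_wilcoxon}}{two-sided Wilcoxon rank-sum test across
#'   individual cells. Ignores sample structure and is anti-conservative
#'   when cells within a sample are correlated; provided for comparison.}
#' }
#' Log2 fold changes are \code{log2((mean_stim + pseudocount) /
#' (mean_ctrl + pseudocount))} on the normalised scale. P-values are
#' Holm-adjusted within each cluster. Clusters missing one condition get
#' \code{NA} rows and a warning.
#'
#' @param counts Gene-by-cell count matrix (dense or sparse, rownames =
#'   genes), or a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param metadata data.frame with columns \code{cell}, \code{sample},
#'   \code{condition} (\code{control}/\code{stimulated}) and \code{cluster};
#'   taken from \code{colData} when \code{counts} is a SingleCellExperiment.
#' @param method \code{"pseudobulk_t"} or \code{"percell_wilcoxon"}.
#' @param pseudocount Added to both normalised means before the log ratio.
#' @return data.frame with columns \code{cluster}, \code{gene},
#'   \code{p_raw}, \code{p_adjusted}, \code{log2fc}, \code{frac_expressing}.
#' @export
clusterDE <- function(counts, metadata = NULL,
                      method = c("pseudobulk_t", "percell_wilcoxon"),
                      pseudocount = 1) {
  method <- match.arg(method)
  if (methods::is(counts, "SingleCellExperiment")) {
    if (is.null(metadata))
      metadata <- as.data.frame(SummarizedExperiment::colData(counts))
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  metadata <- as.data.frame(metadata)
  need <- c("cell", "sample", "condition", "cluster")
  if (!all(need %in% names(metadata)))
    stopDomain("metadata needs columns: ", paste(need, collapse = ", "))
  if (ncol(counts) != nrow(metadata))
    stopDomain("counts columns and metadata rows differ")
  if (!all(metadata$condition %in% c("control", "stimulated")))
    stopDomain("condition must be 'control' or 'stimulated'")
  stimSamples <- unique(metadata$sample[metadata$condition == "stimulated"])
  ctrlSamples <- unique(metadata$sample[metadata$condition == "control"])
  if (length(stimSamples) < 2L || length(ctrlSamples) < 2L)
    stopDomain("need at least 2 samples per condition")

  norm <- .cp10k(counts)
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(nrow(counts)))
  clusters <- sort(unique(metadata$cluster))
  out <- vector("list", length(clusters))

  for (i in seq_along(clusters)) {
    k <- clusters[i]
    inK <- metadata$cluster == k
    frac <- as.numeric(Matrix::rowMeans(counts[, inK, drop = FALSE] > 0))
    condK <- metadata$condition[inK]
    if (!all(c("control", "stimulated") %in% condK)) {
      warning("cluster ", k, " lacks one condition; rows marked undefined")
      out[[i]] <- data.frame(cluster = k, gene = genes, p_raw = NA_real_,
                             p_adjusted = NA_real_, log2fc = NA_real_,
                             frac_expressing = frac)
      next
    }
    normK <- norm[, inK, drop = FALSE]
    if (method == "pseudobulk_t") {
      sampK <- metadata$sample[inK]
      sampleMeans <- sapply(unique(sampK), function(s)
        as.numeric(Matrix::rowMeans(normK[, sampK == s, drop = FALSE])))
      sampCond <- metadata$condition[inK][match(unique(sampK), sampK)]
      S <- sampleMeans[, sampCond == "stimulated", drop = FALSE]
      C <- sampleMeans[, sampCond == "control", drop = FALSE]
      nS <- ncol(S); nC <- ncol(C)
      mS <- rowMeans(S); mC <- rowMeans(C)
      vS <- rowSums((S - mS)^2) / (nS - 1)
      vC <- rowSums((C - mC)^2) / (nC - 1)
      df <- nS + nC - 2
      se <- sqrt(((nS - 1) * vS + (nC - 1) * vC) / df * (1 / nS + 1 / nC))
      tt <- (mS - mC) / se
      p <- 2 * stats::pt(-abs(tt), df)
      p[se == 0 & mS == mC] <- 1
      p[se == 0 & mS != mC] <- .Machine$double.xmin
      lfc <- log2((mS + pseudocount) / (mC + pseudocount))
    } else {
      isStim <- condK == "stimulated"
      p <- apply(normK, 1, function(x) {
        if (all(x == x[1])) return(1)
        stats::wilcox.test(x[isStim], x[!isStim], exact = FALSE)$p.value
      })
      mS <- Matrix::rowMeans(normK[, isStim, drop = FALSE])
      mC <- Matrix::rowMeans(normK[, !isStim, drop = FALSE])
      lfc <- log2((mS + pseudocount) / (mC + pseudocount))
    }
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    out[[i]] <- data.frame(cluster = k, gene = genes, p_raw = as.numeric(p),
                           p_adjusted = holmBonferroni(as.numeric(p)),
                           log2fc = as.numeric(lfc),
                           frac_expressing = frac)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- IEG activation score ----------------------------------------------

#' Signed IEG activation score for one cluster
#'
#' From a cluster's differential-expression rows, the usable panel genes are
#' those expressed in at least \code{minFrac} of the cluster's cells
#' (inclusive) with raw p-value strictly below \code{alpha}. With no usable
#' gene the score is exactly 0. Otherwise the usable raw p-values are
#' combined by \code{\link{fisherCombine}} and the score magnitude is
#' \code{-log10} of the combined p-value (default mode) or of the
#' chi-squared combination statistic (\code{scoreMode =
#' "neglog_chi2_statistic"}); the sign is flipped to negative when the mean
#' log2 fold change of the usable genes is negative, indicating potential
#' inhibition rather than activation. Raw, not multiplicity-adjusted,
#' p-values enter the score; panel genes absent from the table count as not
#' expressed. P-values that underflow to 0 are clamped to the smallest
#' positive double with a warning.
#'
#' @param de Differential-expression rows (\code{\link{clusterDE}} format)
#'   for a single cluster.
#' @param params A \code{\link{ScoreParams}}.
#' @return One-row data.frame: \code{cluster}, \code{score},
#'   \code{n_iegs_used}, \code{combined_p}, \code{mean_log2fc}, \code{sign}.
#' @export
iegActivationScore <- function(de, params = ScoreParams()) {
  de <- as.data.frame(de)
  if (length(unique(de$cluster)) > 1L)
    stopDomain("iegActivationScore expects rows of a single cluster")
  clusterId <- if (nrow(de)) de$cluster[1] else NA
  rows <- de[de$gene %in% params@iegPanel & !is.na(de$p_raw), , drop = FALSE]
  if (any(rows$p_raw == 0)) {
    warning("p-values of 0 clamped to the smallest positive double")
    rows$p_raw[rows$p_raw == 0] <- .Machine$double.xmin
  }
  usable <- rows$frac_expressing >= params@minFrac & rows$p_raw < params@alpha
  zero <- data.frame(cluster = clusterId, score = 0, n_iegs_used = 0L,
                     combined_p = NA_real_, mean_log2fc = NA_real_, sign = 0L)
  if (!any(usable)) return(zero)
  used <- rows[usable, , drop = FALSE]
  fc <- fisherCombine(used$p_raw)
  meanLfc <- mean(used$log2fc)
  magnitude <- switch(params@scoreMode,
    neglog_combined_p = -log10(max(fc$combined_p, .Machine$double.xmin)),
    neglog_chi2_statistic = -log10(fc$statistic))
  sgn <- if (meanLfc < 0) -1L else 1L
  data.frame(cluster = clusterId, score = sgn * magnitude,
             n_iegs_used = sum(usable), combined_p = fc$combined_p,
             mean_log2fc = meanLfc, sign = sgn)
}

#' Score all clusters of a differential-expression table
#'
#' Applies \code{\link{iegActivationScore}} to each cluster.
#'
#' @param de Full \code{\link{clusterDE}}-format table.
#' @param params A \code{\link{ScoreParams}}.
#' @return data.frame with one scored row per cluster.
#' @export
scoreClusters <- function(de, params = ScoreParams()) {
  de <- as.data.frame(de)
  clusters <- sort(unique(de$cluster))
  res <- do.call(rbind, lapply(clusters, function(k)
    iegActivationScore(de[de$cluster == k, , drop = FALSE], params)))
  rownames(res) <- NULL
  res
}

#' Rank clusters by IEG activation score
#'
#' Sorts descending by score; ties are broken by ascending combined p-value
#' (missing combined p last), then by cluster id — in an all-zero table the
#' cluster-id order is therefore arbitrary but stable.
#'
#' @param scores A \code{\link{scoreClusters}} table.
#' @param topN Number of top cluster ids to return (default 4).
#' @return Vector of the \code{topN} highest-scoring cluster ids.
#' @export
rankClusters <- function(scores, topN = 4L) {
  if (topN < 1L) stopDomain("topN must be >= 1")
  scores <- as.data.frame(scores)
  cp <- scores$combined_p
  cp[is.na(cp)] <- Inf
  ord <- order(-scores$score, cp, scores$cluster)
  utils::head(scores$cluster[ord], topN)
}
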