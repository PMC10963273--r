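metricRow <- function(cell = "c1", umi = 2000, genes = 900, mito = 0.02)
  data.frame(cell = cell, umi_count = umi, gene_count = genes,
             mito_fraction = mito)

test_that("QC removal bounds are exclusive, retention bounds inclusive", {
  expect_length(qcFilterCells(metricRow(umi = 799)), 0)        # removed
  expect_equal(qcFilterCells(metricRow(umi = 800, genes = 500, mito = 0.10)), "c1")
  expect_length(qcFilterCells(metricRow(genes = 499)), 0)
  expect_length(qcFilterCells(metricRow(mito = 0.1000001)), 0)
  expect_length(qcFilterCells(metricRow()[0, ]), 0)            # empty in, empty out
})

test_that("QC rejects malformed metrics", {
  expect_error(qcFilterCells(metricRow(umi = -1)), "non-negative")
  expect_error(qcFilterCells(metricRow(mito = 1.2)), "0, 1")
  expect_error(qcFilterCells(metricRow(umi = NA)), "finite")
  expect_error(qcFilterCells(data.frame(cell = "c1")), "columns")
})

test_that("Holm adjustment matches the literal step-down oracle", {
  expect_equal(holmBonferroni(0.03), 0.03)                     # m = 1
  expect_equal(holmBonferroni(c(0.01, 0.04)), c(0.02, 0.04))   # hand-derived
  withr::with_seed(41, {
    for (i in 1:10) {
      p <- runif(sample(2:12, 1))
      adj <- holmBonferroni(p)
      expect_equal(adj, holmOracle(p))
      expect_true(all(adj >= p))                               # dominance
      expect_true(all(adj <= pmin(1, length(p) * p)))          # <= Bonferroni
      perm <- sample(length(p))
      expect_equal(holmBonferroni(p[perm]), adj[perm])         # permutation equivariance
    }
  })
  expect_error(holmBonferroni(c(0.5, 0)), "\\(0, 1]")
})

test_that("Fisher combination matches the closed-form even-df chi-squared tail", {
  expect_equal(fisherCombine(1), list(statistic = 0, df = 2L, combined_p = 1))
  withr::with_seed(43, {
    for (p1 in runif(5))
      expect_equal(fisherCombine(p1)$combined_p, p1)           # k = 1 identity
    for (i in 1:10) {
      p <- runif(sample(2:10, 1))
      fc <- fisherCombine(p)
      expect_equal(fc$statistic, -2 * sum(log(p)))
      expect_equal(fc$df, 2L * length(p))
      expect_equal(fc$combined_p, chisqUpperEvenDf(fc$statistic, length(p)),
                   tolerance = 1e-12)
    }
  })
  fc <- fisherCombine(c(0.01, 0.04))
  expect_equal(fc$statistic, 15.65, tolerance = 1e-3)
  expect_equal(fc$combined_p, chisqUpperEvenDf(fc$statistic, 2), tolerance = 1e-12)
  expect_error(fisherCombine(numeric()), "at least one")
  expect_error(fisherCombine(c(0.2, 1.3)), "\\(0, 1]")
})

test_that("decreasing any input p strictly decreases the combined p", {
  withr::with_seed(45, {
    for (i in 1:10) {
      p <- runif(4, 0.05, 0.9)
      j <- sample(4, 1)
      p2 <- p; p2[j] <- p[j] * 0.5
      expect_lt(fisherCombine(p2)$combined_p, fisherCombine(p)$combined_p)
    }
  })
})

deRow <- function(cluster, gene, p, lfc, frac = 0.5)
  data.frame(cluster = cluster, gene = gene, p_raw = p,
             p_adjusted = pmin(1, p * 10), log2fc = lfc, frac_expressing = frac)

test_that("clusters with no usable panel gene score exactly zero", {
  de <- deRow(1, iegPanelDefault(), p = rep(0.5, 10), lfc = 1)
  row <- iegActivationScore(de)
  expect_identical(row$score, 0)
  expect_identical(row$n_iegs_used, 0L)
  expect_identical(row$sign, 0L)
  # significant but under-expressed genes are also unusable
  de2 <- deRow(1, iegPanelDefault(), p = rep(0.001, 10), lfc = 1, frac = 0.04)
  expect_identical(iegActivationScore(de2)$score, 0)
  # non-panel genes never contribute
  de3 <- deRow(1, c("Gapdh", "Actb"), p = c(1e-8, 1e-8), lfc = 3)
  expect_identical(iegActivationScore(de3)$score, 0)
})

test_that("the expression filter is inclusive at 5% and significance strict at alpha", {
  de <- deRow(1, c("Fos", "Junb"), p = c(0.01, 0.04), lfc = 1,
              frac = c(0.05, 0.049))
  expect_equal(iegActivationScore(de)$n_iegs_used, 1L)         # Junb below 5%
  de2 <- deRow(1, "Fos", p = 0.05, lfc = 1)
  expect_identical(iegActivationScore(de2)$score, 0)           # p = alpha fails
})

test_that("score magnitude composes Fisher with -log10 and the sign follows mean log2FC", {
  de <- deRow(1, c("Fos", "Junb"), p = c(0.01, 0.04), lfc = c(1, 1))
  row <- iegActivationScore(de)
  stat <- -2 * (log(0.01) + log(0.04))
  expect_equal(row$score, -log10(chisqUpperEvenDf(stat, 2)), tolerance = 1e-10)
  expect_equal(row$combined_p, chisqUpperEvenDf(stat, 2), tolerance = 1e-12)
  # negative mean log2FC flips the sign
  deNeg <- deRow(1, c("Fos", "Junb"), p = c(0.01, 0.04), lfc = c(-2, 0.5))
  rowNeg <- iegActivationScore(deNeg)
  expect_equal(rowNeg$score, -row$score)
  expect_identical(rowNeg$sign, -1L)
  # literal statistic mode
  rowStat <- iegActivationScore(de, ScoreParams(scoreMode = "neglog_chi2_statistic"))
  expect_equal(rowStat$score, -log10(stat))
})

test_that("the score ignores expression fractions once genes pass the filter", {
  de1 <- deRow(1, c("Fos", "Jun"), p = c(0.02, 0.03), lfc = 1, frac = c(0.3, 0.6))
  de2 <- deRow(1, c("Fos", "Jun"), p = c(0.02, 0.03), lfc = 1, frac = c(0.9, 0.08))
  expect_equal(iegActivationScore(de1)$score, iegActivationScore(de2)$score)
})

test_that("missing panel genes are treated as not expressed, and p = 0 is clamped", {
  de <- deRow(1, "Fos", p = 0.01, lfc = 1)                     # other 9 absent
  expect_equal(iegActivationScore(de)$n_iegs_used, 1L)
  deZero <- deRow(1, c("Fos", "Jun"), p = c(0.01, 1), lfc = 1)
  deZero$p_raw[2] <- 0
  expect_warning(row <- iegActivationScore(deZero), "clamped")
  expect_true(is.finite(row$score))
})

test_that("pseudobulk DE finds planted panel effects and honours table contracts", {
  sce <- simulateSnRnaSeq(SnRnaSimSpec(nGenes = 300L, nClusters = 3L,
                                       cellsPerCluster = 200L,
                                       activatedClusters = 1L,
                                       inhibitedClusters = 2L, seed = 20L))
  de <- clusterDE(sce)
  expect_true(all(de$p_adjusted >= de$p_raw, na.rm = TRUE))
  expect_equal(nrow(de), 3 * 300)
  expect_false(any(duplicated(de[c("cluster", "gene")])))
  panel <- de[de$gene %in% iegPanelDefault(), ]
  expect_true(mean(panel$p_raw[panel$cluster == 1] < 0.05) > 0.8)
  expect_true(mean(panel$log2fc[panel$cluster == 1]) > 1)
  expect_true(mean(panel$log2fc[panel$cluster == 2]) < -1)
  expect_true(all(abs(panel$log2fc[panel$cluster == 3]) < 1))
  # all-zero genes report zero expression fraction
  zeroGenes <- de$gene[de$frac_expressing == 0 & de$cluster == 1]
  if (length(zeroGenes)) {
    counts <- SummarizedExperiment::assay(sce)
    inK <- SummarizedExperiment::colData(sce)$cluster == 1
    expect_true(all(Matrix::rowSums(counts[zeroGenes, inK, drop = FALSE]) == 0))
  }
})

test_that("genes with identical per-sample means get log2fc 0 under pseudobulk", {
  # 2 samples per condition, constant normalised expression everywhere
  counts <- matrix(5L, nrow = 3, ncol = 8,
                   dimnames = list(c("Fos", "g1", "g2"), paste0("c", 1:8)))
  meta <- data.frame(cell = paste0("c", 1:8),
                     sample = rep(c("s1", "s2", "s3", "s4"), each = 2),
                     condition = rep(c("control", "stimulated"), each = 4),
                     cluster = 1)
  de <- clusterDE(counts, meta)
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p_raw == 1))
})

test_that("a cluster lacking one condition is marked undefined with a warning", {
  set.seed(3)
  counts <- matrix(rpois(48, 4), nrow = 4,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:12)))
  meta <- data.frame(cell = paste0("c", 1:12),
                     sample = c(rep(c("s1", "s2", "s3", "s4"), each = 2),
                                "s3", "s3", "s4", "s4"),
                     condition = c(rep(c("control", "stimulated"), each = 4),
                                   rep("stimulated", 4)),
                     cluster = rep(c(1, 2), c(8, 4)))
  expect_warning(de <- clusterDE(counts, meta), "lacks one condition")
  expect_true(all(is.na(de$p_raw[de$cluster == 2])))
  expect_true(all(!is.na(de$frac_expressing)))
})

test_that("the per-cell Wilcoxon route recovers a strong planted effect", {
  sce <- simulateSnRnaSeq(SnRnaSimSpec(nGenes = 150L, nClusters = 2L,
                                       cellsPerCluster = 120L,
                                       activatedClusters = 1L,
                                       inhibitedClusters = integer(),
                                       iegLog2fc = 2, seed = 22L))
  de <- clusterDE(sce, method = "percell_wilcoxon")
  panel1 <- de[de$cluster == 1 & de$gene %in% iegPanelDefault(), ]
  expect_true(all(panel1$p_raw < 0.05))
  expect_true(mean(panel1$log2fc) > 1)
})

test_that("cluster ranking orders by score with documented tie-breaks", {
  scores <- data.frame(cluster = 1:5, score = c(0, 0, 0, 0, 0),
                       n_iegs_used = 0L, combined_p = NA_real_,
                       mean_log2fc = NA_real_, sign = 0L)
  expect_equal(rankClusters(scores, 4), 1:4)                   # full tie: id order
  scores$score <- c(1, 3, 3, -2, 0)
  scores$combined_p <- c(0.1, 0.01, 0.001, 0.5, NA)
  expect_equal(rankClusters(scores, 4), c(3L, 2L, 1L, 5L))     # p breaks the 3-3 tie
  expect_length(rankClusters(scores, 2), 2)
  expect_error(rankClusters(scores, 0), "topN")
})
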