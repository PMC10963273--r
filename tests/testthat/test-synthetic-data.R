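smallSpec <- function(...) {
  args <- list(shape = c(20L, 20L, 20L), regionDensities = c(`1` = 60),
               noiseSd = 0, seed = 5L)
  args[names(list(...))] <- list(...)
  do.call(VolumeSimSpec, args)
}

test_that("zero region densities plant no cells", {
  sim <- simulateVolume(smallSpec(regionDensities = c(`1` = 0, `2` = 0)))
  expect_equal(nCells(sim$cells), 0L)
  expect_equal(sum(sim$regionCounts$nCells), 0)
})

test_that("identical specs reproduce bit-identical volumes", {
  s <- smallSpec(noiseSd = 2)
  a <- simulateVolume(s); b <- simulateVolume(s)
  expect_identical(gridData(a$volume), gridData(b$volume))
  expect_identical(a$cells@voxels, b$cells@voxels)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulateVolume(s)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("noiseless planted single-voxel cells are recalled perfectly by the detector", {
  sim <- simulateVolume(smallSpec(cellMargin = 0.4))
  det <- gridData(detectFosVoxels(sim$volume, sim$mask))
  truthIdx <- do.call(rbind, sim$cells@voxels)
  # exclude planted cells whose peaks collide within one neighbourhood
  isolated <- vapply(seq_len(nrow(truthIdx)), function(i) {
    sum(abs(truthIdx[, 1] - truthIdx[i, 1]) <= 1 &
        abs(truthIdx[, 2] - truthIdx[i, 2]) <= 1 &
        abs(truthIdx[, 3] - truthIdx[i, 3]) <= 1) == 1
  }, logical(1))
  expect_gt(sum(isolated), 0)
  hit <- det[truthIdx[isolated, , drop = FALSE]]
  expect_true(all(hit))           # 100% recall on isolated interior cells
  # precision: nothing flagged outside planted voxels
  bg <- det; bg[truthIdx] <- FALSE
  expect_equal(sum(bg), 0)
})

test_that("a margin below the detector threshold is invisible (negative control)", {
  sim <- simulateVolume(smallSpec(cellMargin = 0.10))
  expect_gt(nCells(sim$cells), 0)
  expect_equal(sum(gridData(detectFosVoxels(sim$volume, sim$mask))), 0)
})

test_that("planted counts per region converge to the requested densities", {
  dens <- c(`1` = 30, `2` = 80)
  sim <- simulateVolume(VolumeSimSpec(shape = c(40L, 40L, 60L),
                                      regionDensities = dens, seed = 8L))
  regionVoxels <- table(gridData(sim$labels))
  for (i in seq_along(dens)) {
    lambda <- dens[i] * regionVoxels[[as.character(i)]] * voxelVolumeUl(c(25, 25, 25))
    got <- sim$regionCounts$nCells[i]
    expect_lt(abs(got - lambda), 3 * sqrt(lambda))   # Poisson +-3 SE
  }
})

test_that("multi-voxel planted cells are connected and within the 1-8 size rule", {
  sim <- simulateVolume(smallSpec(cellSizeRange = c(3L, 8L), seed = 9L))
  expect_true(all(cellSizes(sim$cells) %in% 3:8))
  for (vox in sim$cells@voxels) {
    comp <- bruteComponents(local({
      a <- array(FALSE, c(20, 20, 20)); a[vox] <- TRUE; a
    }), 26)
    expect_equal(length(comp), 1L)
  }
})

test_that("unnamed region densities are a configuration error", {
  expect_error(VolumeSimSpec(regionDensities = c(40, 40)), "named")
  expect_error(simulateVolume(smallSpec(regionDensities = c(a = 40))), "integer region labels")
})

test_that("cohorts contain n volumes per group with group-specific densities", {
  spec <- CohortSimSpec(base = smallSpec(),
                        densitiesA = c(`1` = 80), densitiesB = c(`1` = 0),
                        nPerGroup = 4L)
  co <- simulateCohort(spec)
  expect_length(co$groupA, 4L)
  expect_length(co$groupB, 4L)            # 8 volumes total
  expect_true(all(sapply(co$groupA, function(m) nCells(m$cells)) > 0))
  expect_true(all(sapply(co$groupB, function(m) nCells(m$cells)) == 0))
  expect_error(CohortSimSpec(base = smallSpec(), nPerGroup = 1L), "nPerGroup")
})

test_that("snRNA-seq simulation is deterministic and respects its geometry", {
  spec <- SnRnaSimSpec(nGenes = 200L, nClusters = 3L, cellsPerCluster = 50L,
                       activatedClusters = 1L, inhibitedClusters = 2L, seed = 4L)
  a <- simulateSnRnaSeq(spec); b <- simulateSnRnaSeq(spec)
  expect_identical(as.matrix(SummarizedExperiment::assay(a)),
                   as.matrix(SummarizedExperiment::assay(b)))
  expect_equal(dim(a), c(200L, 150L))
  cd <- SummarizedExperiment::colData(a)
  expect_equal(sort(unique(cd$condition)), c("control", "stimulated"))
  expect_equal(length(unique(cd$sample)), 4L)       # 2 per condition
  expect_true(all(iegPanelDefault() %in% rownames(a)))
})

test_that("a null effect size yields an all-zero truth table", {
  spec <- SnRnaSimSpec(nGenes = 150L, nClusters = 2L, cellsPerCluster = 30L,
                       activatedClusters = integer(), inhibitedClusters = integer(),
                       iegLog2fc = 0, seed = 6L)
  sce <- simulateSnRnaSeq(spec)
  expect_true(all(S4Vectors::metadata(sce)$truth$log2fc == 0))
})

test_that("library sizes stay within the configured range up to NB variability", {
  sce <- simulateSnRnaSeq(SnRnaSimSpec(nGenes = 400L, nClusters = 2L,
                                       cellsPerCluster = 100L, seed = 10L,
                                       librarySizeRange = c(3000L, 5000L)))
  umi <- SummarizedExperiment::colData(sce)$umi_count
  # per-cell totals are NB sums around the drawn library size
  expect_gt(mean(umi), 3000 * 0.9)
  expect_lt(mean(umi), 5000 * 1.1)
})

test_that("effect clusters must exist and the panel must fit", {
  expect_error(SnRnaSimSpec(nClusters = 2L, activatedClusters = 5L), "existing cluster")
  expect_error(SnRnaSimSpec(nGenes = 5L), "too small")
  expect_error(SnRnaSimSpec(activatedClusters = 1L, inhibitedClusters = 1L), "both")
})

test_that("simulated experiments serialise to MatrixMarket with sidecars", {
  dir <- withr::local_tempdir()
  sce <- simulateSnRnaSeq(SnRnaSimSpec(nGenes = 120L, nClusters = 2L,
                                       cellsPerCluster = 20L, seed = 12L))
  writeSnRnaSeq(sce, dir)
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  expect_equal(dim(m), dim(sce))
  expect_equal(readLines(file.path(dir, "genes.tsv")), rownames(sce))
  meta <- read.delim(file.path(dir, "meta.tsv"))
  expect_equal(nrow(meta), ncol(sce))
})
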