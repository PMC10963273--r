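# config validation: every block has a closed key set; unknown keys are a
# hard error so that typos never silently fall back to defaults
.allowedKeys <- list(
  top = c("pipeline", "seed", "out_dir", "cohort", "detection", "density",
          "compare", "snrnaseq", "qc", "de", "score", "rank"),
  cohort = c("shape", "voxel_size", "background_level", "noise_sd",
             "cell_margin", "cell_size_range", "densities_a", "densities_b",
             "n_per_group"),
  detection = c("threshold_fraction", "comparison_mode", "min_cluster_voxels",
                "max_cluster_voxels", "connectivity"),
  density = "kernel_extent",
  compare = c("variant", "alpha"),
  snrnaseq = c("n_genes", "n_clusters", "cells_per_cluster",
               "samples_per_condition", "ieg_panel", "activated_clusters",
               "inhibited_clusters", "ieg_log2fc", "dispersion",
               "library_size_range", "mito_fraction_range"),
  qc = c("min_umis", "min_genes", "max_mito_fraction"),
  de = c("method", "pseudocount"),
  score = c("ieg_panel", "min_frac", "alpha", "score_mode"),
  rank = "top_n")

.checkKeys <- function(block, name) {
  if (is.null(block)) return(invisible())
  bad <- setdiff(names(block), .allowedKeys[[name]])
  if (length(bad))
    stopDomain("unknown configuration key(s) in '", name, "': ",
               paste(bad, collapse = ", "))
  invisible()
}

#' Read and validate a pipeline run configuration
#'
#' Parses a YAML (or JSON) run configuration, rejecting unknown keys at
#' every level. A configuration selects one of two pipelines:
#' \code{pipeline: fos} (simulate cohort, detect, density, compare,
#' summarise) or \code{pipeline: ieg} (simulate snRNA-seq, QC, differential
#' expression, score, rank). Every stage block is optional and falls back
#' to the package defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopDomain("no such configuration file: ", path)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @param config Configuration list (as from \code{yaml::read_yaml}).
#' @rdname readRunConfig
#' @export
validateRunConfig <- function(config) {
  .checkKeys(config, "top")
  if (is.null(config$pipeline) || !config$pipeline %in% c("fos", "ieg"))
    stopDomain("configuration key 'pipeline' must be 'fos' or 'ieg'")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stopDomain("configuration key 'out_dir' is required")
  for (blk in intersect(names(config), names(.allowedKeys)[-1]))
    .checkKeys(config[[blk]], blk)
  config
}

.cfgOr <- function(x, default) if (is.null(x)) default else x

.logEvent <- function(con, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), event = event),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  message("[fosmap] ", event)
}

#' Run a configured pipeline end to end
#'
#' Executes the stages of the selected pipeline in dependency order, writes
#' every artifact plus a copy of the configuration and a JSON-lines event
#' log into \code{out_dir}, and finishes with \code{manifest.json} listing
#' each artifact with its MD5 content hash. Reruns with an identical
#' configuration (seed included) are bit-identical for all deterministic
#' stages. The master \code{seed} drives every stage: simulation specs
#' receive it directly, so per-mouse seeds follow the documented
#' \code{seed + 1000*(group-1) + mouse} scheme of
#' \code{\link{simulateCohort}}.
#'
#' @param config Configuration list or path to a YAML file
#'   (see \code{\link{readRunConfig}}).
#' @return The manifest, invisibly: a named list of artifact MD5 hashes.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  else config <- validateRunConfig(config)
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  logCon <- file(file.path(outDir, "events.jsonl"), open = "wt")
  on.exit(close(logCon))
  artifacts <- c("config.yaml")

  if (config$pipeline == "fos") {
    cc <- .cfgOr(config$cohort, list())
    base <- VolumeSimSpec(
      shape = .cfgOr(cc$shape, c(48L, 48L, 48L)),
      voxelSize = .cfgOr(cc$voxel_size, c(25, 25, 25)),
      backgroundLevel = .cfgOr(cc$background_level, 100),
      noiseSd = .cfgOr(cc$noise_sd, 2),
      cellMargin = .cfgOr(cc$cell_margin, 0.4),
      cellSizeRange = .cfgOr(cc$cell_size_range, c(1L, 1L)),
      regionDensities = unlist(.cfgOr(cc$densities_a, list(`1` = 40, `2` = 40, `3` = 40))),
      seed = config$seed)
    spec <- CohortSimSpec(
      base = base,
      densitiesA = unlist(.cfgOr(cc$densities_a, list(`1` = 40, `2` = 40, `3` = 40))),
      densitiesB = unlist(.cfgOr(cc$densities_b, list(`1` = 40, `2` = 40, `3` = 40))),
      nPerGroup = .cfgOr(cc$n_per_group, 4L))
    dc <- .cfgOr(config$detection, list())
    dpar <- DetectionParams(
      thresholdFraction = .cfgOr(dc$threshold_fraction, 0.20),
      comparisonMode = .cfgOr(dc$comparison_mode, "each-neighbor"),
      minClusterVoxels = .cfgOr(dc$min_cluster_voxels, 1L),
      maxClusterVoxels = .cfgOr(dc$max_cluster_voxels, 8L),
      connectivity = .cfgOr(dc$connectivity, 26L))
    kpar <- DensityParams(.cfgOr(config$density$kernel_extent, 20L))
    variant <- .cfgOr(config$compare$variant, "student")
    alpha <- .cfgOr(config$compare$alpha, 0.05)

    .logEvent(logCon, "simulate_cohort", n_per_group = spec@nPerGroup)
    cohort <- simulateCohort(spec)
    .logEvent(logCon, "detect_and_density")
    densify <- function(mice, tag) {
      lapply(seq_along(mice), function(i) {
        m <- mice[[i]]
        cells <- findCells(detectFosVoxels(m$volume, m$mask, dpar))
        dm <- localDensity(cellsToCounts(cells, voxelSize = voxelSize(m$volume)), kpar)
        f <- sprintf("density_%s_%d.nii.gz", tag, i)
        writeVolume(Volume3D(gridData(dm), voxelSize(dm)), file.path(outDir, f))
        artifacts <<- c(artifacts, f)
        dm
      })
    }
    dA <- densify(cohort$groupA, "groupA")
    dB <- densify(cohort$groupB, "groupB")
    .logEvent(logCon, "voxelwise_ttest", variant = variant)
    sm <- voxelwiseTTest(dA, dB, variant = variant)
    pArr <- sm@p; pArr[!sm@defined] <- 1  # NIfTI cannot carry the NA marker
    writeVolume(Volume3D(pArr, voxelSize(dA[[1]])), file.path(outDir, "pmap.nii.gz"))
    artifacts <- c(artifacts, "pmap.nii.gz")
    .logEvent(logCon, "summarize_regions", alpha = alpha)
    regions <- summarizeRegions(sm, cohort$labels, alpha = alpha)
    utils::write.table(regions, file.path(outDir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLabelTable(cohort$labels@labelTable, file.path(outDir, "labels.tsv"))
    artifacts <- c(artifacts, "regions.tsv", "labels.tsv")
  } else {
    sc <- .cfgOr(config$snrnaseq, list())
    spec <- SnRnaSimSpec(
      nGenes = .cfgOr(sc$n_genes, 1000L),
      nClusters = .cfgOr(sc$n_clusters, 6L),
      cellsPerCluster = .cfgOr(sc$cells_per_cluster, 400L),
      samplesPerCondition = .cfgOr(sc$samples_per_condition, 2L),
      iegPanel = .cfgOr(sc$ieg_panel, iegPanelDefault()),
      activatedClusters = .cfgOr(sc$activated_clusters, 1L),
      inhibitedClusters = .cfgOr(sc$inhibited_clusters, 2L),
      iegLog2fc = .cfgOr(sc$ieg_log2fc, 1.5),
      dispersion = .cfgOr(sc$dispersion, 0.15),
      librarySizeRange = .cfgOr(sc$library_size_range, c(2000L, 8000L)),
      mitoFractionRange = .cfgOr(sc$mito_fraction_range, c(0, 0.08)),
      seed = config$seed)
    qc <- .cfgOr(config$qc, list())
    qpar <- QCParams(minUmis = .cfgOr(qc$min_umis, 800L),
                     minGenes = .cfgOr(qc$min_genes, 500L),
                     maxMitoFraction = .cfgOr(qc$max_mito_fraction, 0.10))
    spar <- ScoreParams(
      iegPanel = .cfgOr(config$score$ieg_panel, spec@iegPanel),
      minFrac = .cfgOr(config$score$min_frac, 0.05),
      alpha = .cfgOr(config$score$alpha, 0.05),
      scoreMode = .cfgOr(config$score$score_mode, "neglog_combined_p"))

    .logEvent(logCon, "simulate_snrnaseq", n_cells = spec@nClusters * spec@cellsPerCluster)
    sce <- simulateSnRnaSeq(spec)
    writeSnRnaSeq(sce, outDir)
    artifacts <- c(artifacts, "matrix.mtx", "genes.tsv", "barcodes.tsv",
                   "meta.tsv", "truth.tsv")
    .logEvent(logCon, "qc_filter")
    meta <- as.data.frame(SummarizedExperiment::colData(sce))
    kept <- qcFilterCells(meta, qpar)
    if (length(kept) == 0L)
      stopDomain("QC removed every cell; check qc thresholds against the ",
                 "simulated library sizes and gene count")
    sceQ <- sce[, meta$cell %in% kept]
    .logEvent(logCon, "cluster_de", method = .cfgOr(config$de$method, "pseudobulk_t"),
              cells_kept = length(kept))
    de <- clusterDE(sceQ, method = .cfgOr(config$de$method, "pseudobulk_t"),
                    pseudocount = .cfgOr(config$de$pseudocount, 1))
    utils::write.table(de, file.path(outDir, "de_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .logEvent(logCon, "score_and_rank")
    scores <- scoreClusters(de, spar)
    utils::write.table(scores, file.path(outDir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ranked <- rankClusters(scores, topN = .cfgOr(config$rank$top_n, 4L))
    writeLines(as.character(ranked), file.path(outDir, "ranked_clusters.txt"))
    artifacts <- c(artifacts, "de_table.tsv", "scores.tsv", "ranked_clusters.txt")
  }

  manifest <- as.list(tools::md5sum(file.path(outDir, artifacts)))
  names(manifest) <- artifacts
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .logEvent(logCon, "done", artifacts = length(artifacts))
  invisible(manifest)
}
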