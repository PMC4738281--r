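# File-based pipeline orchestration: each step reads the standard formats,
# writes its outputs plus a manifest, and returns its results invisibly.
# A thin command-line dispatcher over these functions ships in
# inst/scripts/barcodePipeline.R.

.writeManifest <- function(dir, step, params, seed = NULL) {
  lines <- c(sprintf("step\t%s", step),
             sprintf("package_version\t%s",
                     as.character(utils::packageVersion("barcodeDelim"))),
             sprintf("r_version\t%s", R.version.string),
             if (!is.null(seed)) sprintf("seed\t%d", as.integer(seed)),
             vapply(names(params), function(k)
               paste0(k, "\t", paste(format(params[[k]]), collapse = ",")),
               character(1L)))
  writeLines(lines, file.path(dir, paste0(step, "_manifest.txt")))
  invisible(NULL)
}

#' Run the simulation step
#'
#' Wraps [generateDataset()]: writes the six dataset files and a manifest to
#' `outDir`.
#'
#' @param outDir output directory (created if missing).
#' @param config a [simulationConfig()].
#' @param seed root seed.
#' @return the [SyntheticDataset-class], invisibly.
#' @export
runSimulate <- function(outDir, config = simulationConfig(), seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ds <- generateDataset(config, dir = outDir, seed = seed)
  .writeManifest(outDir, "simulate", unclass(config), seed = seed)
  invisible(ds)
}

#' Run the species-delimitation step
#'
#' Reads an aligned FASTA (and, optionally, an ultrametric chronogram for
#' the GMYC model; without one a UPGMA tree built from the K2P matrix is
#' used, with a message), runs the three delimitation methods and their
#' consensus, and writes: the NJ tree with bootstrap supports
#' (`nj_tree.nwk`), the three method partitions and the consensus
#' (`partition_*.tsv`), the GMYC report and profile, the K2P matrix, and a
#' manifest.
#'
#' @param alignmentPath path to the aligned FASTA.
#' @param outDir output directory.
#' @param chronogramPath optional Newick ultrametric tree whose tips match
#'   the alignment ids.
#' @param distThreshold,supportMin thresholds of the NJ clustering rule
#'   (defaults 0.02 and 70).
#' @param bootstrapReplicates NJ bootstrap replicates (default 1000).
#' @param abgd an [abgdConfig()].
#' @param seed root seed (bootstrap resampling).
#' @return invisibly, a list with the four partitions, the NJ tree, and the
#'   [GMYCResult-class].
#' @export
runDelimit <- function(alignmentPath, outDir, chronogramPath = NULL,
                       distThreshold = 0.02, supportMin = 70,
                       bootstrapReplicates = 1000L, abgd = abgdConfig(),
                       seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  aln <- readFastaAlignment(alignmentPath)
  dm <- k2pMatrix(aln)
  njTree <- bootstrapNJ(aln, replicates = bootstrapReplicates, seed = seed)
  clusterPart <- clusterByThreshold(njTree, dm,
                                    distThreshold = distThreshold,
                                    supportMin = supportMin)
  abgdRes <- abgdPartitions(dm, abgd)
  abgdPart <- abgdModalPartition(abgdRes)
  if (is.null(chronogramPath)) {
    message("runDelimit: no chronogram supplied; using a UPGMA tree for GMYC")
    gmycTree <- buildUPGMA(dm)
  } else {
    gmycTree <- readNewickTree(chronogramPath)
    if (!setequal(gmycTree$tip.label, sampleIds(aln)))
      stop("chronogram tips do not match alignment ids")
  }
  gmyc <- gmycFit(gmycTree)
  consensus <- consensusPartition(list(clusterPart, abgdPart,
                                       gmycPartition(gmyc)))
  writeNewickTree(njTree, file.path(outDir, "nj_tree.nwk"))
  writeDistanceMatrix(dm, file.path(outDir, "k2p_matrix.tsv"))
  writePartition(clusterPart, file.path(outDir, "partition_cluster.tsv"))
  writePartition(abgdPart, file.path(outDir, "partition_abgd.tsv"))
  writePartition(gmycPartition(gmyc), file.path(outDir, "partition_gmyc.tsv"))
  writePartition(consensus, file.path(outDir, "partition_consensus.tsv"))
  writeGmycReport(gmyc, file.path(outDir, "gmyc_report.txt"),
                  file.path(outDir, "gmyc_profile.tsv"))
  .writeManifest(outDir, "delimit",
                 list(alignment = alignmentPath,
                      chronogram = chronogramPath %||% "(UPGMA fallback)",
                      dist_threshold = distThreshold,
                      support_min = supportMin,
                      bootstrap_replicates = bootstrapReplicates,
                      abgd_pmin = abgd$pMin, abgd_pmax = abgd$pMax,
                      abgd_steps = abgd$nSteps,
                      abgd_gap_x = abgd$relativeGapX), seed = seed)
  invisible(list(cluster = clusterPart, abgd = abgdPart,
                 gmyc = gmyc, consensus = consensus, njTree = njTree,
                 dm = dm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the ecology summary step
#'
#' Reads a partition and a metadata table (plus the alignment for the K2P
#' matrix) and writes the divergence-by-band, divergence-by-environment,
#' richness-by-band, richness-by-host, occupancy, and grid-richness tables.
#'
#' @param alignmentPath aligned FASTA path.
#' @param partitionPath two-column partition TSV.
#' @param metadataPath metadata TSV.
#' @param outDir output directory.
#' @param bands elevation band edges in metres.
#' @param cellDeg grid cell size in decimal degrees.
#' @return invisibly, a named list of the six summary tables.
#' @export
runSummarize <- function(alignmentPath, partitionPath, metadataPath, outDir,
                         bands = .defaultBands(), cellDeg = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  aln <- readFastaAlignment(alignmentPath)
  partition <- readPartition(partitionPath)
  meta <- readSampleMetadata(metadataPath)
  dm <- k2pMatrix(aln)
  divBand <- divergenceByBand(dm, partition, meta, bands = bands)
  divEnv <- divergenceByEnvironment(dm, partition, meta)
  richBand <- richnessByBand(partition, meta, bands = bands)
  richHost <- richnessByHost(partition, meta)
  occ <- occupancySummary(partition, meta)
  grid <- gridRichness(partition, meta, cellDeg = cellDeg)
  wt <- function(x, f) utils::write.table(x, file.path(outDir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(divBand, "divergence_by_band.tsv")
  wt(divEnv, "divergence_by_environment.tsv")
  wt(richBand, "richness_by_band.tsv")
  wt(richHost, "richness_by_host.tsv")
  wt(occ$histogram, "occupancy_histogram.tsv")
  wt(grid, "grid_richness.tsv")
  .writeManifest(outDir, "summarize",
                 list(alignment = alignmentPath, partition = partitionPath,
                      metadata = metadataPath,
                      bands = paste(bands, collapse = ","),
                      cell_deg = cellDeg))
  invisible(list(divergenceByBand = divBand, divergenceByEnvironment = divEnv,
                 richnessByBand = richBand, richnessByHost = richHost,
                 occupancy = occ, gridRichness = grid))
}

#' Run the diversification-rate step
#'
#' Reads an ultrametric chronogram, fits the five rate models, and writes
#' the per-model fit table, the rate-constancy statistic, and the per-node
#' relative cladogenesis table.
#'
#' @param chronogramPath Newick ultrametric tree path.
#' @param outDir output directory.
#' @param alpha significance level of the RC test.
#' @return invisibly, a list with the [DivRateResult-class] and
#'   [RCResult-class].
#' @export
runDivRate <- function(chronogramPath, outDir, alpha = 0.05) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tree <- readNewickTree(chronogramPath)
  fit <- fitRateModels(branchingTimes(tree))
  rc <- rcTest(tree, alpha = alpha)
  utils::write.table(fit@fits, file.path(outDir, "rate_model_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("delta_aic_rc\t%.10g", deltaAICrc(fit)),
               sprintf("best_model\t%s", fit@bestModel)),
             file.path(outDir, "rate_constancy.txt"))
  utils::write.table(rc@table, file.path(outDir, "rc_test.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "divrate",
                 list(chronogram = chronogramPath, alpha = alpha))
  invisible(list(rateModels = fit, rcTest = rc))
}
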