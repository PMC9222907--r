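#' Assemble a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one validated list.
#' Input is either a directory of raw array TSVs plus sample sheet and
#' annotation, or (when \code{simulate} is given) a synthetic experiment
#' generated on the fly.
#'
#' @param outDir output directory.
#' @param rawDir,sampleSheet,annotation paths to raw-array inputs
#'   (ignored when \code{simulate} is given).
#' @param simulate optional [SimulationConfig-class] — generate the input
#'   instead of reading it.
#' @param gmt character vector of GMT library paths (possibly empty).
#' @param fcThreshold,pThreshold DM thresholds (fold scale / strict p).
#' @param minPM QC retention threshold.
#' @param epsilon raw-intensity floor before log2.
#' @param testVariant \code{"student"} or \code{"welch"}.
#' @param metric,linkage clustering options.
#' @param seed integer seed for the simulation branch.
#' @return a list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(outDir, rawDir = NULL, sampleSheet = NULL,
                           annotation = NULL, simulate = NULL,
                           gmt = character(), fcThreshold = 2,
                           pThreshold = 0.05, minPM = 1L, epsilon = 1.0,
                           testVariant = "student", metric = "euclidean",
                           linkage = "complete", seed = NA_integer_) {
  stopifnot(fcThreshold > 0, pThreshold > 0, minPM >= 0, epsilon > 0)
  if (is.null(simulate) && (is.null(rawDir) || is.null(sampleSheet) ||
                            is.null(annotation)))
    stop("either simulate= or rawDir/sampleSheet/annotation must be given")
  structure(list(outDir = outDir, rawDir = rawDir,
                 sampleSheet = sampleSheet, annotation = annotation,
                 simulate = simulate, gmt = gmt,
                 fcThreshold = fcThreshold, pThreshold = pThreshold,
                 minPM = as.integer(minPM), epsilon = epsilon,
                 testVariant = testVariant, metric = metric,
                 linkage = linkage, seed = as.integer(seed)),
            class = "pipelineConfig")
}

stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
         call. = FALSE))
  cat(sprintf("[%s] %.2fs\n", name, proc.time()[["elapsed"]] - t0),
      file = log, append = TRUE)
  res
}

#' Run the full m6A array analysis pipeline
#'
#' Executes simulate/load, spike-in normalization, QC filtering,
#' %Modified quantification, per-biotype differential methylation,
#' Fisher-exact enrichment against each GMT library, and heatmap/volcano
#' rendering; writes every intermediate table, a plain-text log with
#' per-stage timings, and a JSON manifest with filter-stage counts. Given
#' the same configuration and seed the tables are reproduced byte for
#' byte. While a run is in progress a \code{.stale} marker flags partial
#' outputs; it is removed on success.
#'
#' @param config a [pipelineConfig()] list or path to a YAML file of the
#'   same fields.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    cfg <- yaml::read_yaml(config)
    cfg$simulate <- if (!is.null(cfg$simulate))
      do.call(simulationConfig, cfg$simulate)
    config <- do.call(pipelineConfig, cfg)
  }
  stopifnot(inherits(config, "pipelineConfig"))
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  staleMarker <- file.path(out, ".stale")
  file.create(staleMarker)
  log <- file.path(out, "pipeline.log")
  cat("m6Aarray pipeline run\n", file = log)

  sim <- NULL
  if (!is.null(config$simulate)) {
    simCfg <- config$simulate
    if (!is.na(config$seed)) simCfg@seed <- config$seed
    sim <- stage("simulate", log, {
      s <- simulateExperiment(simCfg)
      writeSimulation(s, file.path(out, "simulated"), simCfg)
      s
    })
    raw <- sim$raw
    annotation <- sim$annotation
  } else {
    raw <- stage("load", log,
                 readRawArrays(config$sampleSheet, dir = config$rawDir))
    annotation <- stage("load", log, readProbeAnnotation(config$annotation))
  }

  norm <- stage("normalize", log,
                spikeinNormalize(raw, epsilon = config$epsilon))
  writeMatrixTSV(assay(norm, "ipLog2"),
                 file.path(out, "ip_log2_normalized.tsv"))
  writeMatrixTSV(assay(norm, "supLog2"),
                 file.path(out, "sup_log2_normalized.tsv"))

  retained <- stage("qc_filter", log, qcFilter(raw, minPM = config$minPM))
  me <- stage("quantify", log,
              percentModified(norm, retained = retained,
                              annotation = annotation))
  writeMatrixTSV(pctModified(me), file.path(out, "pct_modified_matrix.tsv"))

  dm <- stage("differential", log,
              runDifferential(me, variant = config$testVariant,
                              fcThreshold = config$fcThreshold,
                              pThreshold = config$pThreshold))
  for (bt in unique(dm$biotype))
    writeResultsTable(dm[dm$biotype == bt, , drop = FALSE],
                      file.path(out, paste0("dm_", bt, ".tsv")))

  dmGenes <- unique(dm$geneSymbol[dm$direction != "ns" &
                                    dm$biotype == "mRNA"])
  universe <- unique(dm$geneSymbol[dm$biotype == "mRNA"])
  enrichment <- list()
  for (gmtPath in config$gmt) {
    gsc <- stage("enrichment", log, readGMT(gmtPath))
    er <- stage("enrichment", log,
                fisherEnrich(dmGenes, gsc, universe = universe))
    writeResultsTable(er, file.path(out, paste0("enrichment_",
                                                libraryName(gsc), ".tsv")))
    enrichment[[libraryName(gsc)]] <- er
  }

  stage("viz", log, {
    for (bt in unique(dm$biotype)) {
      sub <- dm[dm$biotype == bt, , drop = FALSE]
      volcanoPlot(sub, file.path(out, paste0("volcano_", bt, ".png")),
                  fcThreshold = config$fcThreshold,
                  pThreshold = config$pThreshold)
      dmTx <- sub$transcriptId[sub$direction != "ns"]
      if (length(dmTx) >= 1L)
        renderHeatmap(pctModified(me)[dmTx, , drop = FALSE],
                      file.path(out, paste0("heatmap_", bt, ".png")),
                      groups = sampleGroups(me), metric = config$metric,
                      linkage = config$linkage)
    }
    invisible(NULL)
  })

  dirTab <- table(dm$biotype, dm$direction)
  targetProbes <- sum(!isSpikeIn(raw))
  manifest <- list(
    package = "m6Aarray",
    version = as.character(utils::packageVersion("m6Aarray")),
    seed = config$seed,
    thresholds = list(fc = config$fcThreshold, p = config$pThreshold,
                      minPM = config$minPM, epsilon = config$epsilon,
                      test = config$testVariant),
    counts = list(
      probesIn = nrow(raw),
      spikeInProbes = sum(isSpikeIn(raw)),
      targetProbes = targetProbes,
      qcRetained = length(retained),
      qcFiltered = targetProbes - length(retained),
      transcriptsQuantified = nrow(me),
      transcriptsTested = nrow(dm),
      dm = lapply(rownames(dirTab), function(bt)
        as.list(dirTab[bt, ])) |> stats::setNames(rownames(dirTab))))
  cfgPath <- file.path(out, "config.yaml")
  yaml::write_yaml(list(thresholds = manifest$thresholds,
                        seed = config$seed, gmt = config$gmt), cfgPath)
  manifest$configHash <- unname(tools::md5sum(cfgPath))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.remove(staleMarker)
  invisible(manifest)
}
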