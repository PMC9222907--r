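RAW_COLUMNS <- c(probe = "ProbeID", ip = "IP_raw", sup = "Sup_raw",
                 flag = "Flag", spike = "IsSpikeIn")

#' Read raw two-channel array files
#'
#' Loads one tab-delimited file per array (columns ProbeID, IP_raw,
#' Sup_raw, Flag, IsSpikeIn by default; remappable via \code{columns} for
#' real feature-extraction exports) and aligns all arrays on the probe
#' identifier, so the per-file probe order is irrelevant. A probe missing
#' from any array is an error, never a silent NA.
#'
#' @param sampleSheet data frame (or path to a TSV) with columns
#'   \code{File}, \code{Sample}, \code{Group}; Group must be case/control.
#' @param dir directory against which relative file names are resolved.
#' @param columns named character vector remapping the canonical column
#'   names (names \code{probe}, \code{ip}, \code{sup}, \code{flag},
#'   \code{spike}) to the ones present in the files.
#' @return a \linkS4class{RawArraySet} with samples in sheet order.
#' @export
readRawArrays <- function(sampleSheet, dir = ".", columns = RAW_COLUMNS) {
  if (is.character(sampleSheet) && length(sampleSheet) == 1L) {
    if (!file.exists(sampleSheet))
      stop("sample sheet not found: ", sampleSheet)
    sampleSheet <- utils::read.delim(sampleSheet, stringsAsFactors = FALSE)
  }
  needed <- c("File", "Sample", "Group")
  if (!all(needed %in% colnames(sampleSheet)))
    stop("sample sheet must have columns ", paste(needed, collapse = ", "))
  if (anyDuplicated(sampleSheet$Sample))
    stop("duplicated sample IDs in sample sheet")
  if (!all(sampleSheet$Group %in% GROUP_LEVELS))
    stop("Group must be one of ", paste(GROUP_LEVELS, collapse = "/"))
  columns <- c(columns, RAW_COLUMNS[setdiff(names(RAW_COLUMNS),
                                            names(columns))])

  perArray <- lapply(seq_len(nrow(sampleSheet)), function(i) {
    path <- file.path(dir, sampleSheet$File[i])
    if (!file.exists(path))
      stop("no raw array file for sample ", sampleSheet$Sample[i],
           ": ", path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(unname(columns), colnames(d))
    if (length(miss))
      stop("file ", path, " lacks column(s) ", paste(miss, collapse = ", "))
    d <- d[, unname(columns)]
    names(d) <- names(columns)
    if (anyDuplicated(d$probe))
      stop("duplicate probe ID ", d$probe[duplicated(d$probe)][1],
           " in file ", path)
    badFlag <- !d$flag %in% QC_FLAG_LEVELS
    if (any(badFlag)) {
      i1 <- which(badFlag)[1]
      stop("unknown QC flag token ", sQuote(d$flag[i1]), " in file ",
           path, " line ", i1 + 1L)   # +1 for the header line
    }
    if (any(!is.finite(d$ip) | !is.finite(d$sup) | d$ip < 0 | d$sup < 0))
      stop("negative or non-finite intensity in file ", path)
    d
  })

  probes <- sort(perArray[[1]]$probe)
  for (i in seq_along(perArray)) {
    if (!setequal(perArray[[i]]$probe, probes))
      stop("probe set of sample ", sampleSheet$Sample[i],
           " differs from the first array")
    perArray[[i]] <- perArray[[i]][match(probes, perArray[[i]]$probe), ]
  }

  grab <- function(col) {
    m <- vapply(perArray, function(d) d[[col]],
                if (col == "flag") character(length(probes))
                else numeric(length(probes)))
    m <- matrix(m, nrow = length(probes),
                dimnames = list(probes, sampleSheet$Sample))
    m
  }
  spike <- as.logical(perArray[[1]]$spike)
  RawArraySet(grab("ip"), grab("sup"), grab("flag"), spike,
              sampleSheet$Group)
}

#' Write a RawArraySet as per-array TSV files plus a sample sheet
#'
#' Emits the same format [readRawArrays()] consumes: one
#' \code{<sample>.tsv} per array and a \code{sample_sheet.tsv}.
#'
#' @param raw a \linkS4class{RawArraySet}.
#' @param dir output directory (created if missing).
#' @return the sample-sheet path, invisibly.
#' @export
writeRawArrays <- function(raw, dir) {
  stopifnot(is(raw, "RawArraySet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(colnames(raw), ".tsv")
  for (j in seq_len(ncol(raw))) {
    d <- data.frame(ProbeID = rownames(raw),
                    IP_raw = ipRaw(raw)[, j],
                    Sup_raw = supRaw(raw)[, j],
                    Flag = qcFlags(raw)[, j],
                    IsSpikeIn = isSpikeIn(raw))
    utils::write.table(d, file.path(dir, files[j]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sheet <- data.frame(File = files, Sample = colnames(raw),
                      Group = as.character(sampleGroups(raw)))
  sheetPath <- file.path(dir, "sample_sheet.tsv")
  utils::write.table(sheet, sheetPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sheetPath)
}

#' Write a full synthetic experiment to disk
#'
#' Writes the raw arrays and sample sheet ([writeRawArrays()]), the probe
#' annotation, the ground-truth tables and, when a config is given, the
#' generator configuration as YAML.
#'
#' @param sim result of [simulateExperiment()].
#' @param dir output directory.
#' @param config optional [SimulationConfig-class] to record as YAML.
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir, config = NULL) {
  writeRawArrays(sim$raw, dir)
  ann <- data.frame(ProbeID = sim$annotation$probeId,
                    TranscriptID = sim$annotation$transcriptId,
                    GeneSymbol = sim$annotation$geneSymbol,
                    Biotype = sim$annotation$biotype)
  utils::write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- as.data.frame(sim$truth@transcripts)
  utils::write.table(cbind(probeId = rownames(tr), tr),
                     file.path(dir, "truth_transcripts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc <- sim$truth@arrayScale
  utils::write.table(data.frame(channel = rownames(sc), sc,
                                check.names = FALSE),
                     file.path(dir, "truth_array_scale.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    cfg <- attributes(config)
    cfg <- lapply(slotNames(config), function(s) slot(config, s))
    names(cfg) <- slotNames(config)
    yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  }
  invisible(dir)
}

#' Read a probe annotation table
#'
#' TSV with columns ProbeID, TranscriptID, GeneSymbol, Biotype
#' (mRNA/lncRNA/miRNA). Probe IDs must be unique.
#'
#' @param path annotation file.
#' @return a DataFrame keyed by probe ID.
#' @export
readProbeAnnotation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("ProbeID", "TranscriptID", "GeneSymbol", "Biotype")
  if (!all(needed %in% colnames(d)))
    stop("annotation must have columns ", paste(needed, collapse = ", "))
  if (anyDuplicated(d$ProbeID))
    stop("duplicate probe IDs in annotation: ",
         d$ProbeID[duplicated(d$ProbeID)][1])
  if (!all(d$Biotype %in% BIOTYPE_LEVELS))
    stop("Biotype must be one of ", paste(BIOTYPE_LEVELS, collapse = "/"))
  DataFrame(probeId = d$ProbeID, transcriptId = d$TranscriptID,
            geneSymbol = d$GeneSymbol, biotype = d$Biotype,
            row.names = d$ProbeID)
}

#' Read a GMT gene-set library
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' members. Member symbols are uppercased and deduplicated.
#'
#' @param path GMT file.
#' @param name library name (default: file name without extension).
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, name = sub("\\.gmt$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 0L) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1], " of ", path,
         " has fewer than 3 fields")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  GeneSetCollection(name, sets,
                    descriptions = vapply(parts, `[`, "", 2L))
}

#' Write an analysis results table as TSV
#'
#' Numeric columns are written at full precision; for report-style columns
#' a rounded display companion is added (2 d.p. for log2 fold changes,
#' 3 d.p. for group means), mirroring how such tables are usually printed.
#'
#' @param tab data frame (DM records, enrichment records, ...).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(tab, path) {
  tab <- as.data.frame(tab)
  disp <- function(col, digits)
    if (col %in% names(tab)) sprintf(paste0("%.", digits, "f"), tab[[col]])
  for (col in intersect(c("caseMean", "controlMean"), names(tab)))
    tab[[paste0(col, "Display")]] <- disp(col, 3L)
  if ("log2fc" %in% names(tab))
    tab$log2fcDisplay <- disp("log2fc", 2L)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a labelled numeric matrix as TSV
#'
#' Round-trip safe at full double precision (values are written with 17
#' significant digits).
#'
#' @param mat numeric matrix with dimnames.
#' @param path file path.
#' @return \code{path} (write) or the matrix (read).
#' @export
writeMatrixTSV <- function(mat, path) {
  fmt <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  d <- data.frame(id = rownames(mat), fmt, check.names = FALSE)
  colnames(d) <- c("id", colnames(mat))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1]]
  m
}

#' Published AUD nucleus-accumbens differential methylation table
#'
#' The differentially methylated mRNAs, lncRNAs and miRNAs reported by a
#' published 3-case vs 3-control m6A epitranscriptomic microarray study of
#' postmortem nucleus accumbens in alcohol use disorder, with the printed
#' per-group mean %Modified values, regulation calls, log2 fold changes,
#' p-values and FDR. Bundled as a worked example and as a desk-scale check
#' of the fold-change and classification arithmetic.
#'
#' @return data frame with columns RNA, Biotype, CaseMean, ControlMean,
#'   Regulation, Log2FC, PValue, FDR (one row per reported transcript).
#' @export
audNacDMTable <- function() {
  utils::read.delim(system.file("extdata", "aud_nac_dm_table.tsv",
                                package = "m6Aarray"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published demographic summary of the AUD study samples
#'
#' Printed group means, SDs and two-sample t statistics for the donor
#' demographics of the same study as [audNacDMTable()]. Kept to document
#' that the printed t statistics cannot be recomputed from the printed
#' summary statistics alone.
#'
#' @return data frame, one row per demographic variable.
#' @export
audNacDemographics <- function() {
  utils::read.delim(system.file("extdata", "aud_nac_demographics.tsv",
                                package = "m6Aarray"),
                    stringsAsFactors = FALSE)
}
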