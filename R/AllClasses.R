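#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

QC_FLAG_LEVELS <- c("P", "M", "A")
BIOTYPE_LEVELS <- c("mRNA", "lncRNA", "miRNA")
GROUP_LEVELS <- c("control", "case")

#' Raw two-channel m6A array set
#'
#' Container for raw probe intensities of a MeRIP two-channel array
#' experiment: the Cy5-labelled immunoprecipitated (IP) fraction and the
#' Cy3-labelled supernatant (Sup) fraction, one column per array/sample.
#' Probe-level quality flags (Present/Marginal/Absent) and spike-in markers
#' ride along as an assay and row annotation respectively; the case/control
#' group label is sample metadata.
#'
#' @slot .Data inherits all \linkS4class{SummarizedExperiment} slots; assays
#'   are \code{ipRaw}, \code{supRaw} (non-negative numeric matrices) and
#'   \code{qcFlag} (character matrix with values P/M/A).
#' @export
setClass("RawArraySet", contains = "SummarizedExperiment")

setValidity("RawArraySet", function(object) {
  msg <- character()
  needed <- c("ipRaw", "supRaw", "qcFlag")
  if (!all(needed %in% assayNames(object)))
    return(paste("assays must include", paste(needed, collapse = ", ")))
  for (a in c("ipRaw", "supRaw")) {
    x <- assay(object, a)
    if (length(x) && (!all(is.finite(x)) || any(x < 0)))
      msg <- c(msg, paste(a, "intensities must be finite and non-negative"))
  }
  fl <- assay(object, "qcFlag")
  if (length(fl) && !all(fl %in% QC_FLAG_LEVELS))
    msg <- c(msg, "qcFlag values must be one of P, M, A")
  if (!"isSpikeIn" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain logical column isSpikeIn")
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain column group")
  if (length(msg)) msg else TRUE
})

#' Spike-in normalized log2 intensities
#'
#' Result of [spikeinNormalize()]: per-probe log2 IP and Sup intensities
#' after subtraction of the per-array, per-channel mean log2 spike-in
#' intensity. The subtracted calibration constants are kept in
#' \code{metadata(x)$spikeinLog2Mean} (channels x samples matrix).
#'
#' @export
setClass("NormalizedIntensities", contains = "SummarizedExperiment")

setValidity("NormalizedIntensities", function(object) {
  needed <- c("ipLog2", "supLog2")
  if (!all(needed %in% assayNames(object)))
    return(paste("assays must include", paste(needed, collapse = ", ")))
  cal <- metadata(object)$spikeinLog2Mean
  if (is.null(cal) || !is.matrix(cal) ||
      !identical(rownames(cal), c("cy5", "cy3")))
    return("metadata()$spikeinLog2Mean must be a matrix with rows cy5, cy3")
  TRUE
})

#' Transcript-level %Modified methylation matrix
#'
#' Transcripts x samples matrix of the m6A methylation level statistic
#' %Modified = IP/(IP + Sup), each value a fraction in [0, 1]. Row metadata
#' carries the transcript identifier, gene symbol and RNA biotype
#' (mRNA/lncRNA/miRNA); column metadata carries the case/control group.
#'
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  msg <- character()
  if (!"pctMod" %in% assayNames(object))
    return("assay pctMod is required")
  x <- assay(object, "pctMod")
  if (length(x) && !all(is.na(x) | (is.finite(x) & x >= 0 & x <= 1)))
    msg <- c(msg, "pctMod values must lie in [0, 1] (NA allowed)")
  if (!all(c("geneSymbol", "biotype") %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must contain geneSymbol and biotype")
  if (length(msg)) msg else TRUE
})

#' Named gene-set collection
#'
#' A library of gene sets (as read from a GMT file) for over-representation
#' analysis. Member symbols are stored deduplicated and uppercased.
#'
#' @slot name library name (e.g. "GO_BP", "KEGG").
#' @slot sets named list of character vectors of member gene symbols.
#' @slot descriptions per-set description strings, parallel to \code{sets}.
#' @export
setClass("GeneSetCollection",
  representation(name = "character", sets = "list",
                 descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must be uniquely named")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must parallel sets")
  if (any(vapply(object@sets, length, 0L) == 0L))
    msg <- c(msg, "empty gene sets are not allowed")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "set members must be deduplicated")
  if (length(msg)) msg else TRUE
})

#' Synthetic experiment configuration
#'
#' Parameters of the synthetic two-channel m6A array generator. The defaults
#' describe a desk-scale version of a 3 case vs 3 control postmortem brain
#' study: per-transcript baseline methylation fractions drawn from a Beta
#' distribution, a subset of transcripts with a case-specific shift applied
#' on the log-odds scale, log-normal total-RNA abundance, per-array
#' per-channel multiplicative scale factors carried by spike-in probes, and
#' log-normal measurement noise.
#'
#' @export
setClass("SimulationConfig",
  representation(
    nMrna = "integer", nLncrna = "integer", nMirna = "integer",
    nSpikein = "integer", nCase = "integer", nControl = "integer",
    baselineAlpha = "numeric", baselineBeta = "numeric",
    nDM = "integer", effectLogOdds = "numeric",
    abundanceLogMean = "numeric", abundanceLogSd = "numeric",
    arrayScaleLogSd = "numeric", noiseLogSd = "numeric",
    flagAbsentProb = "numeric", flagMarginalProb = "numeric",
    spikeinLadder = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(object@nMrna, object@nLncrna, object@nMirna, object@nSpikein,
           object@nCase, object@nControl, object@nDM)
  if (any(cnt < 0L)) msg <- c(msg, "counts must be non-negative")
  if (object@baselineAlpha <= 0 || object@baselineBeta <= 0)
    msg <- c(msg, "baselineAlpha and baselineBeta must be > 0")
  if (object@flagAbsentProb < 0 || object@flagAbsentProb > 1)
    msg <- c(msg, "flagAbsentProb must lie in [0, 1]")
  if (object@flagMarginalProb < 0 || object@flagMarginalProb > 1)
    msg <- c(msg, "flagMarginalProb must lie in [0, 1]")
  if (object@nDM > object@nMrna + object@nLncrna + object@nMirna)
    msg <- c(msg, "nDM cannot exceed the total transcript count")
  if (any(c(object@abundanceLogSd, object@arrayScaleLogSd,
            object@noiseLogSd) < 0))
    msg <- c(msg, "log-sd parameters must be non-negative")
  if (any(object@spikeinLadder <= 0))
    msg <- c(msg, "spike-in ladder abundances must be positive")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic experiment
#'
#' @slot transcripts per-transcript truth: baseline fraction, planted case
#'   fraction, DM indicator, biotype, gene symbol.
#' @slot arrayScale per-array per-channel multiplicative scale factors
#'   (channels cy5/cy3 x samples).
#' @export
setClass("SimulationTruth",
  representation(transcripts = "DataFrame", arrayScale = "matrix"))

setValidity("SimulationTruth", function(object) {
  tr <- object@transcripts
  needed <- c("transcriptId", "geneSymbol", "biotype",
              "baselineFraction", "caseFraction", "isDM")
  if (!all(needed %in% colnames(tr)))
    return(paste("transcripts must contain", paste(needed, collapse = ", ")))
  f <- c(tr$baselineFraction, tr$caseFraction)
  if (length(f) && (any(f <= 0) || any(f >= 1)))
    return("truth fractions must lie strictly inside (0, 1)")
  if (!identical(rownames(object@arrayScale), c("cy5", "cy3")))
    return("arrayScale must have rows cy5, cy3")
  TRUE
})

#' Agglomerative clustering result
#'
#' Merge sequence, heights and leaf order of a hierarchical clustering of
#' one axis of a matrix, together with the distance metric and linkage used.
#' Convertible to a base \code{hclust} object with [as.hclust()].
#'
#' @export
setClass("DendrogramResult",
  representation(merge = "matrix", height = "numeric", order = "integer",
                 labels = "character", metric = "character",
                 linkage = "character"))

setValidity("DendrogramResult", function(object) {
  n <- length(object@labels)
  if (n >= 2L) {
    if (!identical(sort(object@order), seq_len(n)))
      return("order must be a permutation of the items")
    if (nrow(object@merge) != n - 1L || length(object@height) != n - 1L)
      return("merge/height must describe n - 1 agglomerations")
  }
  TRUE
})
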