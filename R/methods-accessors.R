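#' @describeIn RawArraySet-class raw Cy5/IP intensity matrix.
#' @export
setMethod("ipRaw", "RawArraySet", function(x) assay(x, "ipRaw"))

#' @describeIn RawArraySet-class raw Cy3/Sup intensity matrix.
#' @export
setMethod("supRaw", "RawArraySet", function(x) assay(x, "supRaw"))

#' @describeIn RawArraySet-class character matrix of P/M/A detection flags.
#' @export
setMethod("qcFlags", "RawArraySet", function(x) assay(x, "qcFlag"))

#' @describeIn RawArraySet-class logical vector marking spike-in probes.
#' @export
setMethod("isSpikeIn", "RawArraySet", function(x) rowData(x)$isSpikeIn)

#' @describeIn RawArraySet-class factor of case/control group labels.
#' @export
setMethod("sampleGroups", "RawArraySet", function(x) colData(x)$group)

#' @describeIn NormalizedIntensities-class spike-in markers carried over
#'   from the raw set.
#' @export
setMethod("isSpikeIn", "NormalizedIntensities",
          function(x) rowData(x)$isSpikeIn)

#' @describeIn NormalizedIntensities-class group labels.
#' @export
setMethod("sampleGroups", "NormalizedIntensities",
          function(x) colData(x)$group)

#' @describeIn NormalizedIntensities-class channels x samples matrix of the
#'   subtracted mean log2 spike-in intensities.
#' @export
setMethod("spikeinLog2Mean", "NormalizedIntensities",
          function(x) metadata(x)$spikeinLog2Mean)

#' @describeIn MethylationExperiment-class transcripts x samples matrix of
#'   %Modified fractions.
#' @export
setMethod("pctModified", "MethylationExperiment",
          function(x) assay(x, "pctMod"))

#' @describeIn MethylationExperiment-class RNA biotype per transcript.
#' @export
setMethod("biotype", "MethylationExperiment", function(x) rowData(x)$biotype)

#' @describeIn MethylationExperiment-class group labels.
#' @export
setMethod("sampleGroups", "MethylationExperiment",
          function(x) colData(x)$group)

#' @describeIn GeneSetCollection-class named list of member-symbol vectors.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection-class library name.
#' @export
setMethod("libraryName", "GeneSetCollection", function(x) x@name)

#' @describeIn GeneSetCollection-class number of sets in the library.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "RawArraySet", function(object) {
  cat("RawArraySet:", nrow(object), "probes x", ncol(object), "arrays\n")
  cat("  spike-in probes:", sum(isSpikeIn(object)), "\n")
  grp <- table(sampleGroups(object))
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "NormalizedIntensities", function(object) {
  cat("NormalizedIntensities:", nrow(object), "probes x", ncol(object),
      "arrays (log2, spike-in calibrated)\n")
})

setMethod("show", "MethylationExperiment", function(object) {
  cat("MethylationExperiment:", nrow(object), "transcripts x",
      ncol(object), "samples\n")
  bt <- table(factor(biotype(object), BIOTYPE_LEVELS))
  cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  sz <- vapply(object@sets, length, 0L)
  cat("GeneSetCollection", sQuote(object@name), "with", length(sz),
      "sets (sizes", if (length(sz)) paste0(min(sz), "-", max(sz)) else "0",
      ")\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nMrna, "mRNA +", object@nLncrna,
      "lncRNA +", object@nMirna, "miRNA probes,", object@nSpikein,
      "spike-ins\n")
  cat("  design:", object@nCase, "cases vs", object@nControl,
      "controls;", object@nDM, "planted effects of", object@effectLogOdds,
      "log-odds\n")
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@transcripts), "transcripts,",
      sum(object@transcripts$isDM), "planted DM\n")
})

setMethod("show", "DendrogramResult", function(object) {
  cat("DendrogramResult:", length(object@labels), "leaves,",
      object@metric, "distance,", object@linkage, "linkage\n")
})

#' @describeIn DendrogramResult-class convert to a base \code{hclust}
#'   object (e.g. for plotting or \code{cutree}).
#' @param x a \code{DendrogramResult}.
#' @param ... ignored.
#' @importFrom stats as.hclust
#' @export
as.hclust.DendrogramResult <- function(x, ...) {
  structure(list(merge = x@merge, height = x@height, order = x@order,
                 labels = x@labels, method = x@linkage,
                 dist.method = x@metric, call = match.call()),
            class = "hclust")
}

#' @describeIn DendrogramResult-class leaf order (permutation of items).
#' @export
leafOrder <- function(x) {
  stopifnot(is(x, "DendrogramResult"))
  x@order
}

#' @describeIn DendrogramResult-class merge heights, in agglomeration order.
#' @export
mergeHeights <- function(x) {
  stopifnot(is(x, "DendrogramResult"))
  x@height
}
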