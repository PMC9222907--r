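#' @rdname RawArraySet-class
#' @param x a \linkS4class{RawArraySet} (or other container) to access.
#' @export
setGeneric("ipRaw", function(x) standardGeneric("ipRaw"))

#' @rdname RawArraySet-class
#' @export
setGeneric("supRaw", function(x) standardGeneric("supRaw"))

#' @rdname RawArraySet-class
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @rdname RawArraySet-class
#' @export
setGeneric("isSpikeIn", function(x) standardGeneric("isSpikeIn"))

#' @rdname RawArraySet-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname NormalizedIntensities-class
#' @export
setGeneric("spikeinLog2Mean", function(x) standardGeneric("spikeinLog2Mean"))

#' @rdname MethylationExperiment-class
#' @export
setGeneric("pctModified", function(x) standardGeneric("pctModified"))

#' @rdname MethylationExperiment-class
#' @export
setGeneric("biotype", function(x) standardGeneric("biotype"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("libraryName", function(x) standardGeneric("libraryName"))

#' Spike-in normalization of raw two-channel intensities
#'
#' @param x object holding raw intensities.
#' @param ... further arguments.
#' @export
setGeneric("spikeinNormalize", function(x, ...)
  standardGeneric("spikeinNormalize"))

#' QC-flag retention filter
#'
#' @param x object holding QC flags.
#' @param ... further arguments.
#' @export
setGeneric("qcFilter", function(x, ...) standardGeneric("qcFilter"))

#' %Modified methylation-level statistic
#'
#' @param x object holding normalized intensities.
#' @param ... further arguments.
#' @export
setGeneric("percentModified", function(x, ...)
  standardGeneric("percentModified"))
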