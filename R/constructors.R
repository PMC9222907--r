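#' Construct a RawArraySet
#'
#' @param ipRaw,supRaw numeric probe x sample matrices of raw Cy5 (IP) and
#'   Cy3 (Sup) intensities; identical dimnames.
#' @param qcFlag character matrix of P/M/A detection flags, same shape.
#' @param isSpikeIn logical vector, one entry per probe.
#' @param group case/control label per sample (coerced to a factor with
#'   levels control, case).
#' @return a \linkS4class{RawArraySet}.
#' @examples
#' ip <- matrix(2^(6:11), 3, 2, dimnames = list(paste0("PR", 1:3), c("s1", "s2")))
#' ras <- RawArraySet(ip, ip / 2, matrix("P", 3, 2), c(FALSE, FALSE, TRUE),
#'                    c("case", "control"))
#' ras
#' @export
RawArraySet <- function(ipRaw, supRaw, qcFlag, isSpikeIn, group) {
  ipRaw <- as.matrix(ipRaw)
  supRaw <- as.matrix(supRaw)
  qcFlag <- as.matrix(qcFlag)
  stopifnot(identical(dim(ipRaw), dim(supRaw)),
            identical(dim(ipRaw), dim(qcFlag)),
            length(isSpikeIn) == nrow(ipRaw),
            length(group) == ncol(ipRaw))
  dimnames(supRaw) <- dimnames(qcFlag) <- dimnames(ipRaw)
  se <- SummarizedExperiment(
    assays = list(ipRaw = ipRaw, supRaw = supRaw, qcFlag = qcFlag),
    rowData = DataFrame(isSpikeIn = as.logical(isSpikeIn),
                        row.names = rownames(ipRaw)),
    colData = DataFrame(group = factor(group, levels = GROUP_LEVELS),
                        row.names = colnames(ipRaw)))
  new("RawArraySet", se)
}

#' Construct a GeneSetCollection
#'
#' Member symbols are uppercased and deduplicated; empty sets are rejected.
#'
#' @param name library name.
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional description per set (default the set name).
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(name, sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, function(m) unique(toupper(as.character(m))))
  if (is.null(descriptions)) descriptions <- names(sets)
  new("GeneSetCollection", name = as.character(name), sets = sets,
      descriptions = as.character(descriptions))
}

# internal: wrap normalized assays
newNormalizedIntensities <- function(ipLog2, supLog2, rowData, colData,
                                     spikeinLog2Mean, flooredCount) {
  se <- SummarizedExperiment(
    assays = list(ipLog2 = ipLog2, supLog2 = supLog2),
    rowData = rowData, colData = colData)
  metadata(se)$spikeinLog2Mean <- spikeinLog2Mean
  metadata(se)$flooredCount <- flooredCount
  new("NormalizedIntensities", se)
}

# internal: wrap a %Modified matrix
newMethylationExperiment <- function(pctMod, geneSymbol, biotype, colData) {
  se <- SummarizedExperiment(
    assays = list(pctMod = pctMod),
    rowData = DataFrame(geneSymbol = geneSymbol,
                        biotype = biotype,
                        row.names = rownames(pctMod)),
    colData = colData)
  new("MethylationExperiment", se)
}
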