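#' @describeIn spikeinNormalize calibrate each array/channel against its
#'   spike-in probes.
#'
#' For every array and channel the arithmetic mean of the log2 raw
#' spike-in intensities is subtracted from the log2 raw intensity of every
#' probe:
#' \deqn{log2(IP_{norm}) = log2(IP_{raw}) - mean[log2(IP_{spike,raw})]}
#' and likewise for the Sup/Cy3 channel. Because all probes of one
#' array/channel share the subtracted constant, any multiplicative scale
#' applied to a whole channel (labeling efficiency, scanner gain) cancels
#' exactly. Spike-in probes themselves average to 0 after normalization by
#' construction.
#'
#' Non-positive raw intensities cannot be logged and are floored at
#' \code{epsilon} first; the number of floored values is reported via
#' \code{metadata(x)$flooredCount} and a message.
#'
#' @param x a \linkS4class{RawArraySet}.
#' @param epsilon floor (raw intensity units) applied to non-positive
#'   values before taking log2.
#' @return a \linkS4class{NormalizedIntensities}.
#' @export
setMethod("spikeinNormalize", "RawArraySet", function(x, epsilon = 1.0) {
  stopifnot(epsilon > 0)
  spike <- isSpikeIn(x)
  if (!any(spike))
    stop("no spike-in probes: spike-in normalization impossible")

  floorPos <- function(m) {
    n <- sum(m <= 0)
    m[m <= 0] <- epsilon
    list(m = m, n = n)
  }
  ipF <- floorPos(ipRaw(x))
  supF <- floorPos(supRaw(x))
  nFloored <- ipF$n + supF$n
  if (nFloored > 0)
    message(nFloored, " non-positive intensities floored at epsilon = ",
            epsilon)

  for (j in seq_len(ncol(x))) {
    if (all(ipRaw(x)[spike, j] <= 0) || all(supRaw(x)[spike, j] <= 0))
      stop("array ", colnames(x)[j],
           ": all spike-in intensities are non-positive in one channel")
  }

  ipLog2 <- log2(ipF$m)
  supLog2 <- log2(supF$m)
  calCy5 <- colMeans(ipLog2[spike, , drop = FALSE])
  calCy3 <- colMeans(supLog2[spike, , drop = FALSE])
  ipLog2 <- sweep(ipLog2, 2L, calCy5)
  supLog2 <- sweep(supLog2, 2L, calCy3)

  cal <- rbind(cy5 = calCy5, cy3 = calCy3)
  colnames(cal) <- colnames(x)
  newNormalizedIntensities(ipLog2, supLog2, rowData(x), colData(x),
                           cal, nFloored)
})

#' @describeIn qcFilter retain probes detected on enough arrays.
#'
#' A probe is retained when its QC flag is Present (P) or Marginal (M) in
#' at least \code{minPM} of the arrays — the default 1 reproduces the
#' "P or M in at least 1 out of 6 samples" retention rule used for the
#' "All Targets Value" table of a 6-array study. Spike-in probes are
#' control features and never part of the retained target set.
#'
#' @param x a \linkS4class{RawArraySet}.
#' @param minPM minimum number of arrays with a P or M call.
#' @return character vector of retained probe IDs.
#' @export
setMethod("qcFilter", "RawArraySet", function(x, minPM = 1L) {
  stopifnot(minPM >= 0L)
  nPM <- rowSums(matrix(qcFlags(x) %in% c("P", "M"), nrow = nrow(x)))
  keep <- nPM >= minPM & !isSpikeIn(x)
  retained <- rownames(x)[keep]
  if (!length(retained))
    message("QC filter retained no probes (minPM = ", minPM, ")")
  retained
})

#' @describeIn percentModified the m6A methylation level statistic.
#'
#' Converts the spike-in normalized log2 intensities back to the linear
#' scale and computes, per probe and sample,
#' \deqn{\%Modified = IP / (IP + Sup)}
#' with IP and Sup the normalized linear intensities — the fraction of a
#' transcript's RNA carrying the m6A mark. Probes are restricted to
#' \code{retained} (QC-passing, from [qcFilter()]); spike-ins are always
#' excluded. When an annotation maps several probes to one transcript,
#' probe values are aggregated by the arithmetic mean.
#'
#' @param x a \linkS4class{NormalizedIntensities}.
#' @param retained probe IDs passing QC; \code{NULL} keeps all non-spike-in
#'   probes.
#' @param annotation probe annotation (as from [readProbeAnnotation()] or
#'   [simulateExperiment()]); \code{NULL} treats each probe as its own
#'   transcript with unknown symbol/biotype "mRNA".
#' @return a \linkS4class{MethylationExperiment}.
#' @export
setMethod("percentModified", "NormalizedIntensities",
          function(x, retained = NULL, annotation = NULL) {
  keep <- !isSpikeIn(x)
  if (!is.null(retained)) keep <- keep & rownames(x) %in% retained
  ipLin <- 2^assay(x, "ipLog2")[keep, , drop = FALSE]
  supLin <- 2^assay(x, "supLog2")[keep, , drop = FALSE]
  tot <- ipLin + supLin
  if (any(tot == 0))
    stop("IP + Sup underflowed to zero for ", sum(tot == 0),
         " measurements")
  pm <- ipLin / tot

  probes <- rownames(pm)
  if (is.null(annotation)) {
    ann <- DataFrame(probeId = probes, transcriptId = probes,
                     geneSymbol = probes, biotype = "mRNA",
                     row.names = probes)
  } else {
    unann <- setdiff(probes, rownames(annotation))
    if (length(unann)) {
      message(length(unann), " unannotated probes excluded")
      pm <- pm[setdiff(probes, unann), , drop = FALSE]
    }
    ann <- annotation[rownames(pm), , drop = FALSE]
  }

  tx <- unique(ann$transcriptId)
  if (anyDuplicated(ann$transcriptId)) {
    grp <- factor(ann$transcriptId, levels = tx)
    pm <- rowsum(pm, group = grp) / as.vector(table(grp))
  }
  rownames(pm) <- tx
  first <- match(tx, ann$transcriptId)
  newMethylationExperiment(pm,
                           geneSymbol = ann$geneSymbol[first],
                           biotype = ann$biotype[first],
                           colData = colData(x))
})

#' Run the full quantification stage
#'
#' Convenience wrapper chaining [spikeinNormalize()], [qcFilter()] and
#' [percentModified()].
#'
#' @param raw a \linkS4class{RawArraySet}.
#' @param annotation optional probe annotation.
#' @param epsilon floor for non-positive intensities.
#' @param minPM QC retention threshold.
#' @return a \linkS4class{MethylationExperiment}.
#' @export
quantifyMethylation <- function(raw, annotation = NULL, epsilon = 1.0,
                                minPM = 1L) {
  norm <- spikeinNormalize(raw, epsilon = epsilon)
  retained <- qcFilter(raw, minPM = minPM)
  percentModified(norm, retained = retained, annotation = annotation)
}
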