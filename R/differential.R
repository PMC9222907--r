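#' Two-group t-test on %Modified values
#'
#' Two-sided two-sample t-test comparing case against control values of a
#' single transcript. The default is Student's pooled-variance test (the
#' convention of array-vendor differential workflows); Welch's unequal
#' variance test is selectable. Degenerate inputs where both groups have
#' zero variance are resolved without error: equal means give t = 0,
#' p = 1; unequal means give an infinite t with p = 0 and a warning, since
#' no within-group variability supports the comparison.
#'
#' @param case,control numeric vectors, at least 2 finite values each.
#' @param variant \code{"student"} (pooled variance) or \code{"welch"}.
#' @return named list with \code{statistic} and \code{p.value}.
#' @examples
#' groupTTest(c(0.60, 0.70, 0.68), c(0.30, 0.29, 0.31))
#' @importFrom stats t.test sd
#' @export
groupTTest <- function(case, control, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(case) >= 2L, length(control) >= 2L,
            all(is.finite(case)), all(is.finite(control)))
  if (sd(case) == 0 && sd(control) == 0) {
    d <- mean(case) - mean(control)
    if (d == 0) return(list(statistic = 0, p.value = 1))
    warning("zero variance in both groups with unequal means; ",
            "degenerate t-test")
    return(list(statistic = sign(d) * Inf, p.value = 0))
  }
  tt <- t.test(case, control, var.equal = (variant == "student"))
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Log2 fold change of group mean %Modified
#'
#' \code{log2(caseMean / controlMean)}; both means must be positive
#' (guaranteed upstream by epsilon flooring of raw intensities).
#'
#' @param caseMean,controlMean group means of %Modified (vectorized).
#' @return log2 fold change(s), case over control.
#' @examples
#' log2FoldChange(0.660, 0.293)  # 1.17 at 2 d.p.
#' @export
log2FoldChange <- function(caseMean, controlMean) {
  if (any(caseMean <= 0) || any(controlMean <= 0))
    stop("group means must be positive to form a fold change")
  log2(caseMean / controlMean)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, preserving input
#' order. Thin validated front door over \code{stats::p.adjust}.
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @importFrom stats p.adjust
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify differential methylation direction
#'
#' A transcript is called \code{up} when log2FC >= log2(fcThreshold) and
#' p < pThreshold, \code{down} when log2FC <= -log2(fcThreshold) and
#' p < pThreshold, otherwise \code{ns}. The fold-change bound is
#' inclusive ("at least 2-fold") and the p bound strict, matching the
#' usual |FC| >= 2 and p < 0.05 convention.
#'
#' @param log2fc log2 fold change(s).
#' @param p p-value(s).
#' @param fcThreshold fold-change threshold on the fold scale (2 means
#'   |log2FC| >= 1).
#' @param pThreshold significance threshold (strict).
#' @return factor with levels up, down, ns.
#' @examples
#' classifyDM(c(1.17, 1.00, 0.90), c(0.016, 0.045, 0.001))
#' @export
classifyDM <- function(log2fc, p, fcThreshold = 2, pThreshold = 0.05) {
  stopifnot(fcThreshold > 0, pThreshold > 0, all(is.finite(log2fc)),
            all(is.finite(p)))
  lfc <- log2(fcThreshold)
  out <- rep("ns", length(log2fc))
  out[log2fc >= lfc & p < pThreshold] <- "up"
  out[log2fc <= -lfc & p < pThreshold] <- "down"
  factor(out, levels = c("up", "down", "ns"))
}

#' Per-transcript differential methylation analysis
#'
#' For every transcript of a \linkS4class{MethylationExperiment}, compares
#' case against control %Modified values with [groupTTest()], forms the
#' log2 fold change of group means, classifies the direction at the
#' |FC| >= fcThreshold and p < pThreshold rule, and BH-adjusts p-values
#' within each RNA biotype stratum separately (mRNA, lncRNA and miRNA
#' populate differently sized testing universes).
#'
#' Transcripts with missing values in either group are excluded with a
#' message.
#'
#' @param me a \linkS4class{MethylationExperiment}.
#' @param variant t-test variant, see [groupTTest()].
#' @param fcThreshold,pThreshold DM thresholds, see [classifyDM()].
#' @return data frame of per-transcript records: transcriptId, geneSymbol,
#'   biotype, caseMean, controlMean, log2fc, tStat, pValue, fdr,
#'   direction; input row order.
#' @export
runDifferential <- function(me, variant = c("student", "welch"),
                            fcThreshold = 2, pThreshold = 0.05) {
  stopifnot(is(me, "MethylationExperiment"))
  variant <- match.arg(variant)
  grp <- sampleGroups(me)
  if (sum(grp == "case") < 2L || sum(grp == "control") < 2L)
    stop("need at least 2 samples per group")
  pm <- pctModified(me)
  caseM <- pm[, grp == "case", drop = FALSE]
  ctrlM <- pm[, grp == "control", drop = FALSE]

  complete <- rowSums(is.na(caseM)) == 0L & rowSums(is.na(ctrlM)) == 0L
  if (any(!complete)) {
    message(sum(!complete), " transcripts with missing values excluded")
    caseM <- caseM[complete, , drop = FALSE]
    ctrlM <- ctrlM[complete, , drop = FALSE]
  }
  rd <- rowData(me)[complete, , drop = FALSE]

  tests <- lapply(seq_len(nrow(caseM)), function(i)
    groupTTest(caseM[i, ], ctrlM[i, ], variant = variant))
  caseMean <- rowMeans(caseM)
  controlMean <- rowMeans(ctrlM)
  res <- data.frame(
    transcriptId = rownames(caseM),
    geneSymbol = rd$geneSymbol,
    biotype = rd$biotype,
    caseMean = caseMean,
    controlMean = controlMean,
    log2fc = log2FoldChange(caseMean, controlMean),
    tStat = vapply(tests, `[[`, 0, "statistic"),
    pValue = vapply(tests, `[[`, 0, "p.value"),
    row.names = NULL, stringsAsFactors = FALSE)

  res$fdr <- NA_real_
  for (bt in unique(res$biotype)) {
    i <- res$biotype == bt
    res$fdr[i] <- bhAdjust(res$pValue[i])
  }
  res$direction <- classifyDM(res$log2fc, res$pValue,
                              fcThreshold = fcThreshold,
                              pThreshold = pThreshold)
  res
}
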