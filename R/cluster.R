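#' Agglomerative hierarchical clustering of one matrix axis
#'
#' Clusters the rows (transcripts) or columns (samples) of a methylation
#' matrix by agglomerative hierarchical clustering (via
#' \code{stats::hclust} on a \code{stats::dist} matrix). Defaults —
#' euclidean distance, complete linkage — are the base-R \code{hclust}
#' conventions. The result is deterministic given the input order.
#'
#' @param mat numeric matrix without missing values.
#' @param axis \code{"rows"} or \code{"columns"}.
#' @param metric distance metric accepted by \code{stats::dist}.
#' @param linkage agglomeration method accepted by \code{stats::hclust}.
#' @return a \linkS4class{DendrogramResult}.
#' @examples
#' m <- matrix(c(0, 1, 3), ncol = 1, dimnames = list(c("a", "b", "c"), "s"))
#' hierarchicalCluster(m, "rows")
#' @importFrom stats dist hclust
#' @export
hierarchicalCluster <- function(mat, axis = c("rows", "columns"),
                                metric = "euclidean",
                                linkage = "complete") {
  axis <- match.arg(axis)
  if (axis == "columns") mat <- t(mat)
  if (nrow(mat) < 2L)
    stop("need at least 2 items on the clustered axis")
  if (anyNA(mat)) stop("missing values are not allowed")
  hc <- hclust(dist(mat, method = metric), method = linkage)
  new("DendrogramResult", merge = hc$merge, height = hc$height,
      order = as.integer(hc$order),
      labels = if (is.null(hc$labels))
        as.character(seq_len(nrow(mat))) else hc$labels,
      metric = metric, linkage = linkage)
}

#' Clustered heatmap of %Modified values
#'
#' Renders the classic DM-transcript heatmap: rows and columns ordered by
#' hierarchical clustering ([hierarchicalCluster()]), a red-green
#' gradient mapping high and low methylation levels, and a group color
#' bar over the samples. Alongside the image, the clustering-reordered
#' matrix is written as TSV — the bit-stable artifact; rendering details
#' of the image are not pinned.
#'
#' @param mat transcripts x samples matrix of %Modified values.
#' @param path output image (.png or .pdf).
#' @param groups optional case/control label per column for the color bar.
#' @param metric,linkage clustering options.
#' @return invisibly, a list with the row/column
#'   \linkS4class{DendrogramResult}s (NULL for axes with < 2 items) and
#'   the path of the reordered-matrix TSV.
#' @importFrom grDevices colorRampPalette
#' @export
renderHeatmap <- function(mat, path, groups = NULL, metric = "euclidean",
                          linkage = "complete") {
  rowDend <- if (nrow(mat) >= 2L)
    hierarchicalCluster(mat, "rows", metric, linkage) else NULL
  colDend <- if (ncol(mat) >= 2L)
    hierarchicalCluster(mat, "columns", metric, linkage) else NULL

  ro <- if (is.null(rowDend)) seq_len(nrow(mat)) else leafOrder(rowDend)
  co <- if (is.null(colDend)) seq_len(ncol(mat)) else leafOrder(colDend)
  reordered <- mat[ro, co, drop = FALSE]
  tsvPath <- paste0(tools::file_path_sans_ext(path), "_reordered.tsv")
  writeMatrixTSV(reordered, tsvPath)

  annCol <- NA
  annColors <- NA
  if (!is.null(groups)) {
    annCol <- data.frame(group = factor(groups, GROUP_LEVELS),
                         row.names = colnames(mat))
    annColors <- list(group = c(control = "#377EB8", case = "#E41A1C"))
  }
  pheatmap::pheatmap(
    mat,
    cluster_rows = if (is.null(rowDend)) FALSE else as.hclust(rowDend),
    cluster_cols = if (is.null(colDend)) FALSE else as.hclust(colDend),
    color = colorRampPalette(c("green", "black", "red"))(101),
    annotation_col = annCol, annotation_colors = annColors,
    filename = path, silent = TRUE)
  invisible(list(rowDendrogram = rowDend, colDendrogram = colDend,
                 reorderedMatrix = tsvPath))
}

#' Volcano plot of differential methylation results
#'
#' Plots each transcript at (log2FC, -log10 p); up-regulated transcripts
#' are red, down-regulated green, non-significant gray, with guide lines
#' at the fold-change bounds (x = +/- log2(fcThreshold)) and the p cutoff
#' (y = -log10(pThreshold)). Zero p-values are clamped to the smallest
#' positive double for plotting, with a message.
#'
#' @param dm data frame from [runDifferential()] (columns log2fc, pValue,
#'   direction).
#' @param path output image (.png or .pdf).
#' @param fcThreshold,pThreshold guide-line positions, matching the
#'   classification thresholds.
#' @return invisibly, the ggplot object.
#' @import ggplot2
#' @export
volcanoPlot <- function(dm, path, fcThreshold = 2, pThreshold = 0.05) {
  stopifnot(all(c("log2fc", "pValue", "direction") %in% colnames(dm)))
  p <- dm$pValue
  if (any(p == 0)) {
    message(sum(p == 0), " zero p-values clamped for plotting")
    p[p == 0] <- .Machine$double.xmin
  }
  d <- data.frame(log2fc = dm$log2fc, negLog10P = -log10(p),
                  direction = dm$direction)
  gg <- ggplot(d, aes(x = .data$log2fc, y = .data$negLog10P,
                      color = .data$direction)) +
    geom_point(size = 1) +
    scale_color_manual(values = c(up = "red", down = "green3",
                                  ns = "gray60"), drop = FALSE) +
    geom_vline(xintercept = c(-1, 1) * log2(fcThreshold),
               linetype = "dashed") +
    geom_hline(yintercept = -log10(pThreshold), linetype = "dashed") +
    labs(x = "log2 fold change (case / control)",
         y = "-log10 p-value", color = NULL) +
    theme_bw()
  ggsave(path, gg, width = 5, height = 4, dpi = 150)
  invisible(gg)
}
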