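#' Fisher-exact gene-set over-representation analysis
#'
#' Tests each gene set of a library for over-representation of a list of
#' differentially methylated (DM) gene symbols against a measured-gene
#' universe, using the one-sided ("greater") Fisher exact test — i.e. the
#' hypergeometric upper tail P(X >= k) for the 2x2 table
#' \preformatted{
#'           in set   not in set
#'   DM        k        n - k
#'   not DM  K - k   N - K - n + k
#' }
#' with k DM genes in the set, K universe genes in the set, n DM genes
#' and N universe genes. p-values are BH-adjusted within the library, and
#' records are sorted by ascending p with ties broken alphabetically by
#' set name. The universe should be the symbols actually measured (e.g.
#' all genes with a QC-retained probe), not the whole genome: the array's
#' coverage defines the sampling frame.
#'
#' Symbols are uppercased before matching. DM genes absent from the
#' universe are dropped with a warning; sets with no member in the
#' universe are skipped.
#'
#' @param dmGenes character vector of DM gene symbols.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of measured gene symbols.
#' @return data frame with one row per set: library, set, description,
#'   k, K, n, N, oddsRatio (sample odds ratio of the 2x2 table), pValue,
#'   adjP.
#' @examples
#' gsc <- GeneSetCollection("demo", list(SETA = c("IL6", "OSMR", "ARSA")))
#' fisherEnrich(c("IL6", "OSMR"), gsc, universe = sprintf("G%02d", 1:50))
#' @importFrom stats phyper
#' @export
fisherEnrich <- function(dmGenes, collection, universe) {
  stopifnot(is(collection, "GeneSetCollection"))
  universe <- unique(toupper(universe))
  dmGenes <- unique(toupper(dmGenes))
  outside <- setdiff(dmGenes, universe)
  if (length(outside)) {
    warning(length(outside),
            " DM genes absent from the universe were dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "),
            if (length(outside) > 5L) ", ...")
    dmGenes <- intersect(dmGenes, universe)
  }
  N <- length(universe)
  n <- length(dmGenes)
  if (n == 0L || length(collection) == 0L)
    return(data.frame(library = character(), set = character(),
                      description = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      oddsRatio = numeric(), pValue = numeric(),
                      adjP = numeric()))

  sets <- geneSets(collection)
  rows <- lapply(seq_along(sets), function(i) {
    members <- intersect(sets[[i]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(dmGenes, members))
    # hypergeometric upper tail = one-sided (greater) Fisher exact p
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / ((n - k) * (K - k))
    if (is.nan(or)) or <- 1   # 0/0: degenerate margins, no association
    data.frame(library = libraryName(collection), set = names(sets)[i],
               description = collection@descriptions[i],
               k = k, K = K, n = n, N = N, oddsRatio = or, pValue = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(library = character(), set = character(),
                      description = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      oddsRatio = numeric(), pValue = numeric(),
                      adjP = numeric()))
  res$adjP <- bhAdjust(res$pValue)
  res[order(res$pValue, res$set), , drop = FALSE]
}
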