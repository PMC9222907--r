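suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and where possible the library
# routines) used by the package itself.

# textbook two-sample t-test formulas
tOracle <- function(x, y, variant = "student") {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(statistic = t, p.value = 2 * pt(-abs(t), df))
}

# quadratic-time BH step-up: adj_i = min over {j : p_j >= p_i} of p_j*m/rank_j
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- numeric(m)
  adjSorted <- p[o] * m / seq_len(m)
  for (i in seq_len(m))
    adjSorted[i] <- min(adjSorted[i:m])
  r[o] <- pmin(adjSorted, 1)
  r
}

# hypergeometric upper tail by explicit enumeration over lchoose terms
fisherOracle <- function(k, K, n, N) {
  xs <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# exhaustive-search agglomerative clustering (euclidean), complete or
# average linkage; cluster distances recomputed from scratch each step
refAgglomerate <- function(mat, linkage = "complete") {
  n <- nrow(mat)
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        pair <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dd <- if (linkage == "complete") max(pair) else mean(pair)
        if (dd < bestD) { bestD <- dd; best <- c(i, j) }
      }
    }
    heights[step] <- bestD
    merges[[step]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merges[[step]]
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# leaf sets of the internal nodes of an hclust-style merge matrix
mergeLeafSets <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[i]] <- sort(c(grab(merge[i, 1]), grab(merge[i, 2])))
  }
  sets
}

# canonical string form of a collection of (height, leaf-set) merges
canonMerges <- function(heights, sets) {
  s <- vapply(sets, paste, "", collapse = ",")
  paste(sprintf("%.10g", heights[order(heights, s)]),
        s[order(heights, s)], sep = "@")
}

# small noise-free generator settings shared by several tests
noiseFreeConfig <- function(n = 100, seed = 11, ...) {
  simulationConfig(nMrna = n, nLncrna = 0, nMirna = 0, nDM = 0,
                   noiseLogSd = 0, arrayScaleLogSd = 0,
                   abundanceLogSd = 0, flagAbsentProb = 0, seed = seed,
                   ...)
}
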